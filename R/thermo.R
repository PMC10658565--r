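# Thermal-property extraction and crystallization-propensity
# classification: unfolding peaks (Tm1, Tm2) from thermograms, aggregation
# onsets (Tagg) from static-light-scattering traces, and a three-way
# propensity rule on the Tagg(266 nm) axis.

#' Construct a thermogram
#'
#' @param T_C Strictly increasing temperature grid, degrees C (>= 50
#'   points; instrument scans cover roughly 15-100 C).
#' @param signal Excess-heat signal, arbitrary units.
#' @return Object of class `thermogram`.
#' @export
thermogram <- function(T_C, signal) {
  if (length(T_C) < 50) stop("thermogram needs >= 50 points", call. = FALSE)
  if (any(diff(T_C) <= 0))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  if (length(signal) != length(T_C))
    stop("signal and temperature lengths differ", call. = FALSE)
  structure(list(T_C = T_C, signal = signal), class = "thermogram")
}

#' Construct a static-light-scattering trace
#'
#' @param T_C Strictly increasing temperature grid, degrees C.
#' @param signal Scattering intensity, arbitrary units.
#' @param wavelength 266 (small assemblies) or 473 (large aggregates), nm.
#' @return Object of class `sls_trace`.
#' @export
sls_trace <- function(T_C, signal, wavelength = 266) {
  if (!wavelength %in% c(266, 473))
    stop("wavelength must be 266 or 473 nm", call. = FALSE)
  if (any(diff(T_C) <= 0))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  if (length(signal) != length(T_C))
    stop("signal and temperature lengths differ", call. = FALSE)
  structure(list(T_C = T_C, signal = signal, wavelength = wavelength),
            class = "sls_trace")
}

# peak prominence: height above the higher of the two flanking minima
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- if (p > 1) min(y[1:(p - 1)]) else y[[p]]
    right <- if (p < length(y)) min(y[(p + 1):length(y)]) else y[[p]]
    y[[p]] - max(left, right)
  }, numeric(1))
}

#' Detect the two unfolding events in a thermogram
#'
#' Subtracts a linear baseline fitted to the leading and trailing 10% of the
#' scan, smooths with a Savitzky-Golay filter, locates prominence-filtered
#' local maxima, keeps the two highest separated by at least `min_sep`
#' degrees, and refines each to sub-grid precision with a local quadratic
#' fit.
#'
#' @param tg A [thermogram()].
#' @param min_sep Minimum separation between the two events, degrees C
#'   (default 3).
#' @param prominence_frac Prominence threshold as a fraction of the
#'   baseline-subtracted signal range (default 0.05).
#' @return List with `Tm1 < Tm2` (degrees C) and `n_events`; when only one
#'   peak clears the prominence filter, `Tm2` is `NA` and `n_events` is 1
#'   (flagged single event).
#' @export
detect_unfolding_events <- function(tg, min_sep = 3,
                                    prominence_frac = 0.05) {
  Tg <- tg$T_C; y <- tg$signal
  n <- length(y)
  edge <- seq_len(max(5, round(0.1 * n)))
  idx <- c(edge, n + 1 - edge)
  base_fit <- stats::lm.fit(cbind(1, Tg[idx]), y[idx])
  y0 <- y - (base_fit$coefficients[[1]] + base_fit$coefficients[[2]] * Tg)
  step <- stats::median(diff(Tg))
  # smoothing window ~1 C, odd, cubic Savitzky-Golay
  win <- max(5, 2 * floor(0.5 / step) + 1)
  win <- min(win, 2 * floor((n - 1) / 2) - 1)
  ys <- signal::sgolayfilt(y0, p = min(3, win - 2), n = win)
  peaks <- which(diff(sign(diff(ys))) == -2) + 1
  if (!length(peaks)) return(list(Tm1 = NA_real_, Tm2 = NA_real_,
                                  n_events = 0L))
  prom <- .peak_prominence(ys, peaks)
  keep <- peaks[prom >= prominence_frac * diff(range(ys))]
  if (!length(keep)) keep <- peaks[which.max(prom)]
  ord <- keep[order(ys[keep], decreasing = TRUE)]
  sel <- ord[[1]]
  for (cand in ord[-1]) {
    if (abs(Tg[[cand]] - Tg[[sel[1]]]) >= min_sep) { sel <- c(sel, cand); break }
  }
  refine <- function(i) {
    lo <- max(1, i - 5); hi <- min(n, i + 5)
    w <- lo:hi
    fit <- stats::lm(ys[w] ~ stats::poly(Tg[w], 2, raw = TRUE))
    cf <- stats::coef(fit)
    if (!is.finite(cf[[3]]) || cf[[3]] >= 0) return(Tg[[i]])
    vx <- -cf[[2]] / (2 * cf[[3]])
    if (vx < Tg[[lo]] || vx > Tg[[hi]]) Tg[[i]] else vx
  }
  tms <- sort(vapply(sel, refine, numeric(1)))
  if (length(tms) == 1)
    list(Tm1 = tms[[1]], Tm2 = NA_real_, n_events = 1L)
  else list(Tm1 = tms[[1]], Tm2 = tms[[2]], n_events = 2L)
}

#' Detect the aggregation onset of an SLS trace
#'
#' The onset is the first temperature where the signal exceeds the initial
#' plateau median by `n_sd` robust SDs (MAD-based) and stays above for at
#' least `persistence` consecutive points. A trace that never leaves its
#' baseline has no onset (returns `NA`, not an error). The rule is invariant
#' to uniform scaling of the signal.
#'
#' @param trace An [sls_trace()].
#' @param baseline_frac Leading fraction of the grid treated as the initial
#'   plateau (default 0.25).
#' @param n_sd Exceedance threshold in robust SDs (default 5).
#' @param persistence Required consecutive exceedances (default 3).
#' @return Onset temperature in degrees C, or `NA_real_` when absent.
#' @export
detect_onset <- function(trace, baseline_frac = 0.25, n_sd = 5,
                         persistence = 3) {
  Tg <- trace$T_C; y <- trace$signal
  nb <- max(5, floor(baseline_frac * length(y)))
  base <- y[seq_len(nb)]
  thr <- stats::median(base) + n_sd * stats::mad(base)
  above <- y > thr
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[[i]]) run + 1L else 0L
    if (run >= persistence) return(Tg[[i - persistence + 1L]])
  }
  NA_real_
}

#' Thermal summary of one protein
#'
#' @param Tm1,Tm2 Unfolding event temperatures, degrees C (`Tm1 < Tm2` when
#'   both present).
#' @param Tagg266,Tagg473 Aggregation onsets at 266 / 473 nm, degrees C or
#'   `NA`.
#' @return Object of class `thermal_summary`.
#' @export
thermal_summary <- function(Tm1, Tm2, Tagg266 = NA_real_,
                            Tagg473 = NA_real_) {
  if (!is.na(Tm1) && !is.na(Tm2) && Tm1 >= Tm2)
    stop("Tm1 must be below Tm2", call. = FALSE)
  structure(list(Tm1 = Tm1, Tm2 = Tm2, Tagg266 = Tagg266,
                 Tagg473 = Tagg473), class = "thermal_summary")
}

#' Classify crystallization propensity from thermal properties
#'
#' Three-way partition of the Tagg(266 nm) axis with closed-left/open-right
#' boundaries: below `precip_max` the protein tends to precipitate; from
#' `precip_max` (inclusive) up to `stable_min` (exclusive) it is
#' crystallization-prone, with the `favored` sub-band annotated in the
#' rationale; at or above `stable_min` aggregation is too weak and the
#' protein stays in solution. A missing Tagg(266) is indeterminate. The
#' default thresholds (36.1 / 55.6 C, favored 45-50 C) come from a small
#' observational panel and should be treated as hypothesis-level; all are
#' configurable.
#'
#' @param summary A [thermal_summary()] with `Tm2` present.
#' @param precip_max Upper edge of the precipitation-prone region, C.
#' @param stable_min Lower edge of the solution-stable region, C.
#' @param favored Length-2 band marked "favored" inside the
#'   crystallization-prone region, C.
#' @return List of class `propensity_call` with `label` (one of
#'   `crystallization-prone`, `precipitation-prone`, `solution-stable`,
#'   `indeterminate`) and `rationale`.
#' @export
classify_propensity <- function(summary, precip_max = 36.1,
                                stable_min = 55.6, favored = c(45, 50)) {
  if (is.na(summary$Tm2))
    stop("classification requires Tm2", call. = FALSE)
  tagg <- summary$Tagg266
  if (is.na(tagg)) {
    label <- "indeterminate"
    rationale <- "no Tagg(266 nm) onset available"
  } else if (tagg < precip_max) {
    label <- "precipitation-prone"
    rationale <- sprintf("Tagg(266) = %.1f C < %.1f C: strong early
aggregation", tagg, precip_max)
  } else if (tagg < stable_min) {
    label <- "crystallization-prone"
    in_band <- tagg >= favored[[1]] && tagg < favored[[2]]
    rationale <- sprintf(
      "Tagg(266) = %.1f C in [%.1f, %.1f)%s", tagg, precip_max, stable_min,
      if (in_band) sprintf("; inside the favored %.0f-%.0f C band",
                           favored[[1]], favored[[2]]) else "")
  } else {
    label <- "solution-stable"
    rationale <- sprintf(
      "Tagg(266) = %.1f C >= %.1f C: aggregation tendency too weak",
      tagg, stable_min)
  }
  structure(list(label = label, rationale = gsub("\n", " ", rationale)),
            class = "propensity_call")
}

#' Summarize a set of thermal curves from a manifest
#'
#' The manifest CSV carries `path,protein,curve_type` with `curve_type` in
#' `dsc`, `sls266`, `sls473`; each curve file is a CSV `T_C,signal`. Returns
#' the exchange table `protein,Tm1,Tm2,Tagg266,Tagg473,label`.
#'
#' @param manifest_path Manifest CSV path (curve paths relative to it).
#' @param ... Threshold overrides passed to [classify_propensity()].
#' @return Data.frame, one row per protein.
#' @export
summarize_thermal_curves <- function(manifest_path, ...) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "protein", "curve_type")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  base <- dirname(manifest_path)
  rows <- lapply(split(man, man$protein), function(m) {
    vals <- list(Tm1 = NA_real_, Tm2 = NA_real_,
                 Tagg266 = NA_real_, Tagg473 = NA_real_)
    for (i in seq_len(nrow(m))) {
      cv <- utils::read.csv(file.path(base, m$path[[i]]))
      if (m$curve_type[[i]] == "dsc") {
        ev <- detect_unfolding_events(thermogram(cv$T_C, cv$signal))
        vals$Tm1 <- ev$Tm1; vals$Tm2 <- ev$Tm2
      } else {
        wl <- if (m$curve_type[[i]] == "sls266") 266 else 473
        onset <- detect_onset(sls_trace(cv$T_C, cv$signal, wl))
        if (wl == 266) vals$Tagg266 <- onset else vals$Tagg473 <- onset
      }
    }
    label <- if (is.na(vals$Tm2)) "indeterminate"
      else classify_propensity(thermal_summary(vals$Tm1, vals$Tm2,
                                               vals$Tagg266, vals$Tagg473),
                               ...)$label
    data.frame(protein = m$protein[[1]], Tm1 = vals$Tm1, Tm2 = vals$Tm2,
               Tagg266 = vals$Tagg266, Tagg473 = vals$Tagg473,
               label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
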