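# Time-lapse crystal-dissolution imaging: segmentation of a single crystal
# per field, projected-area tracking, percent-remaining curves,
# complete-dissolution times and one-way ANOVA group comparison.

#' Construct a single microscopy frame
#'
#' @param pixels Numeric matrix of intensities (any scale; normalized
#'   internally).
#' @param pixel_size Pixel edge length, micrometres (> 0).
#' @param timestamp Acquisition time, minutes.
#' @return Object of class `xtal_frame`.
#' @export
xtal_frame <- function(pixels, pixel_size, timestamp) {
  if (!is.matrix(pixels) || !length(pixels))
    stop("pixels must be a non-empty numeric matrix", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 timestamp = timestamp), class = "xtal_frame")
}

#' Construct a time-ordered image stack
#'
#' @param frames List of [xtal_frame()] objects with strictly increasing
#'   timestamps and a uniform pixel size.
#' @param label Crystal / group identifier.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(frames, label = "crystal") {
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  px <- vapply(frames, `[[`, numeric(1), "pixel_size")
  if (any(diff(ts) <= 0))
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  if (length(unique(px)) != 1)
    stop("all frames must share one pixel size", call. = FALSE)
  structure(list(frames = frames, label = label,
                 pixel_size = px[[1]], timestamps = ts),
            class = "image_stack")
}

# merge 4-connected labels that touch diagonally, giving 8-connectivity
.merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2 || nc < 2 || max(lab) <= 1) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[[i, 1]]); rb <- find(pairs[[i, 2]])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

#' Segment the crystal in one frame
#'
#' Global Otsu binarization on the configured contrast polarity, hole
#' filling, and retention of the largest connected component under
#' 8-connectivity. A frame with no usable contrast (constant intensity, or an
#' Otsu split whose class separation is indistinguishable from noise) yields
#' an empty mask with a `low_contrast` warning attribute rather than an
#' exception -- a fully dissolved crystal is a valid observation.
#'
#' @param frame An [xtal_frame()].
#' @param polarity `"dark"` (default; dark crystal on a bright bright-field
#'   background) or `"bright"`.
#' @param min_separation Minimum Otsu class-mean separation in units of the
#'   pooled within-class SD below which the frame is declared objectless
#'   (default 4; splitting pure Gaussian noise gives about 2.7).
#' @return Logical matrix mask; attribute `low_contrast` flags an empty mask
#'   caused by missing contrast.
#' @export
segment_crystal <- function(frame, polarity = c("dark", "bright"),
                            min_separation = 4) {
  polarity <- match.arg(polarity)
  px <- frame$pixels
  rng <- range(px)
  empty <- matrix(FALSE, nrow(px), ncol(px))
  if (diff(rng) < .Machine$double.eps^0.5) {
    warning("constant-intensity frame: no contrast to segment")
    return(structure(empty, low_contrast = TRUE))
  }
  x <- (px - rng[[1]]) / diff(rng)
  if (polarity == "dark") x <- 1 - x
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  mask <- x > thr
  n1 <- sum(mask); n0 <- sum(!mask)
  pooled <- sqrt((stats::var(x[mask]) * (n1 - 1) +
                  stats::var(x[!mask]) * (n0 - 1)) / (n1 + n0 - 2))
  sep <- (mean(x[mask]) - mean(x[!mask])) / pooled
  if (is.nan(sep)) sep <- Inf  # perfectly separated noiseless classes
  if (!any(mask) || all(mask) || sep < min_separation) {
    warning("low-contrast frame: Otsu split indistinguishable from noise")
    return(structure(empty, low_contrast = TRUE))
  }
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- .merge_diagonal_labels(
    as.matrix(EBImage::imageData(EBImage::bwlabel(filled))))
  sizes <- tabulate(lab[lab > 0])
  structure(lab == which.max(sizes), low_contrast = FALSE)
}

#' Projected area of a mask
#'
#' @param mask Logical matrix from [segment_crystal()].
#' @param pixel_size Pixel edge length, micrometres.
#' @return Area in square micrometres (pixel count times pixel area).
#' @export
projected_area <- function(mask, pixel_size) {
  sum(mask) * pixel_size^2
}

#' Percent-remaining area series for a stack
#'
#' Segments every frame, converts mask areas to square micrometres and
#' normalizes to the first frame (= 100%).
#'
#' @param stack An [image_stack()].
#' @param ... Passed to [segment_crystal()].
#' @return Data.frame of class `area_series` with columns `t` (minutes),
#'   `area` (um^2) and `percent_remaining`.
#' @export
percent_remaining_series <- function(stack, ...) {
  areas <- vapply(stack$frames, function(f)
    projected_area(suppressWarnings(segment_crystal(f, ...)),
                   f$pixel_size), numeric(1))
  if (areas[[1]] <= 0)
    stop("first frame yields an empty mask: nothing to normalize",
         call. = FALSE)
  structure(data.frame(t = stack$timestamps, area = areas,
                       percent_remaining = 100 * areas / areas[[1]]),
            class = c("area_series", "data.frame"), label = stack$label)
}

#' Complete-dissolution time from an image stack
#'
#' Timestamp of the first frame whose measured area falls below a detection
#' floor, default 1% of the initial area (sub-resolution remnants are
#' indistinguishable from noise).
#'
#' @param stack An [image_stack()] or a precomputed `area_series`.
#' @param floor_frac Detection floor as a fraction of the initial area.
#' @param ... Passed to [percent_remaining_series()].
#' @return List with `time` (minutes; grid end when censored) and
#'   `censored`.
#' @export
stack_dissolution_time <- function(stack, floor_frac = 0.01, ...) {
  series <- if (inherits(stack, "area_series")) stack
            else percent_remaining_series(stack, ...)
  hit <- which(series$percent_remaining < 100 * floor_frac)
  if (length(hit)) list(time = series$t[[hit[[1]]]], censored = FALSE)
  else list(time = series$t[[nrow(series)]], censored = TRUE)
}

#' One-way ANOVA comparison of dissolution times
#'
#' Standard fixed-effects one-way ANOVA across groups of complete-dissolution
#' times (group sizes may be unequal).
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return List of class `group_comparison` with `group_labels`,
#'   `n_per_group`, `F_statistic`, `df`, `p_value`.
#' @export
compare_groups_anova <- function(groups) {
  if (length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups), n)))
  tab <- stats::anova(stats::aov(y ~ g, data = df))
  Fst <- tab[["F value"]][[1]]
  p <- tab[["Pr(>F)"]][[1]]
  if (is.nan(Fst)) { Fst <- 0; p <- 1 }  # zero between- and within-variance
  structure(list(group_labels = names(groups), n_per_group = unname(n),
                 F_statistic = Fst, df = c(tab$Df[[1]], tab$Df[[2]]),
                 p_value = p),
            class = "group_comparison")
}

# ---- stack IO ---------------------------------------------------------------

#' Write an image stack as TIFF (or PNG) frames plus a manifest
#'
#' Frames go to `<label>_t<minutes>.tif` (32-bit float TIFF; intensities are
#' clamped to [0,1] for PNG). A manifest CSV
#' `path,label,t_min,pixel_size_um` is written alongside.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` or `"png"`.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_image_stack <- function(stack, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- character(length(stack$frames))
  for (i in seq_along(stack$frames)) {
    f <- stack$frames[[i]]
    fn <- file.path(dir, sprintf("%s_t%g.%s", stack$label, f$timestamp, ext))
    if (format == "tiff") tiff::writeTIFF(f$pixels, fn, bits.per.sample = 32)
    else png::writePNG(pmin(pmax(f$pixels, 0), 1), fn)
    paths[[i]] <- fn
  }
  manifest <- file.path(dir, paste0(stack$label, "_manifest.csv"))
  utils::write.csv(data.frame(path = basename(paths), label = stack$label,
                              t_min = stack$timestamps,
                              pixel_size_um = stack$pixel_size),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read an image stack from a manifest CSV or a directory
#'
#' A manifest CSV must carry `path,label,t_min,pixel_size_um` (paths
#' relative to the manifest). A bare directory is scanned for
#' `<label>_t<minutes>.tif/.png`; timestamps are parsed from the filenames,
#' defaulting to 2-minute spacing if absent.
#'
#' @param source Manifest CSV path or directory.
#' @param pixel_size Pixel size override, micrometres (required for the
#'   directory form; default 1).
#' @return An [image_stack()] (single label), or a named list of stacks when
#'   the manifest holds several labels.
#' @export
read_image_stack <- function(source, pixel_size = 1) {
  read_one <- function(path) {
    if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
    else tiff::readTIFF(path)
  }
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "_t[0-9.]+\\.(tif|tiff|png)$",
                        full.names = TRUE)
    if (!length(files)) stop("no frame files found in ", source,
                             call. = FALSE)
    tvals <- as.numeric(sub(".*_t([0-9.]+)\\.[a-z]+$", "\\1", files))
    if (anyNA(tvals)) tvals <- 2 * (seq_along(files) - 1)
    ord <- order(tvals)
    frames <- lapply(ord, function(i)
      xtal_frame(read_one(files[[i]]), pixel_size, tvals[[i]]))
    lbl <- sub("_t[0-9.]+\\.[a-z]+$", "", basename(files[[ord[1]]]))
    return(image_stack(frames, lbl))
  }
  man <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("path", "label", "t_min", "pixel_size_um")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  base <- dirname(source)
  stacks <- lapply(split(man, man$label), function(m) {
    m <- m[order(m$t_min), ]
    frames <- lapply(seq_len(nrow(m)), function(i)
      xtal_frame(read_one(file.path(base, m$path[[i]])),
                 m$pixel_size_um[[i]], m$t_min[[i]]))
    image_stack(frames, m$label[[1]])
  })
  if (length(stacks) == 1) stacks[[1]] else stacks
}
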