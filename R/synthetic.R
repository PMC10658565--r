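# Seeded synthetic-data generators with ground truth: crystal-form tables,
# dissolving-crystal image stacks, two-event thermograms, and SLS traces.
# Identical arguments and seed give bit-identical output.

# run expr with a private RNG state so generators never disturb the
# caller's stream; seedless calls still restore the ambient state
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  if (!is.null(seed)) set.seed(seed)
  expr
}

# the five tabulated crystal forms: printed cell parameters, space groups,
# copies per asymmetric unit, printed cell volume and Matthews coefficient
.CRYSTAL_TABLE <- list(
  list(name = "mNb-WT",     a = 31.468, b = 39.369, c = 39.952,
       alpha = 102.140, beta = 90.231, gamma = 90.948,
       sg = "P1",      copies = 2L, V_printed = 48380.15, vm = 1.76),
  list(name = "mutant 2",   a = 31.220, b = 41.090, c = 74.050,
       alpha = 90, beta = 90, gamma = 90,
       sg = "P212121", copies = 1L, V_printed = 94993.55, vm = 1.73),
  list(name = "mutant 7",   a = 24.985, b = 53.267, c = 65.364,
       alpha = 90, beta = 90, gamma = 90,
       sg = "P212121", copies = 1L, V_printed = 86662.6,  vm = 1.57),
  list(name = "analogue 1", a = 30.326, b = 38.419, c = 38.781,
       alpha = 101.846, beta = 90.036, gamma = 92.225,
       sg = "P1",      copies = 2L, V_printed = 44186.2,  vm = 1.59),
  list(name = "analogue 2", a = 30.381, b = 38.201, c = 38.773,
       alpha = 102.137, beta = 90.1, gamma = 92.211,
       sg = "P1",      copies = 2L, V_printed = 43958.52, vm = 1.58)
)

#' Reference crystal-form table
#'
#' Builds the five tabulated polymorphs of the anti-VEGF nanobody panel
#' (wild type, two surface mutants, two humanized analogues) with molar
#' masses back-filled by [infer_molar_mass()] from the tabulated cell
#' volumes and Matthews coefficients. Optionally appends randomized
#' orthorhombic variants for property testing.
#'
#' @param n_random Number of extra randomized forms (default 0).
#' @param seed RNG seed for the randomized variants.
#' @return List of [crystal_form()] objects. Each reference form carries the
#'   tabulated volume and Matthews coefficient in attributes
#'   `V_printed` / `vm_printed`.
#' @export
make_crystal_table <- function(n_random = 0, seed = NULL) {
  forms <- lapply(.CRYSTAL_TABLE, function(r) {
    f <- crystal_form(r$name,
                      unit_cell(r$a, r$b, r$c, r$alpha, r$beta, r$gamma),
                      space_group(r$sg), r$copies)
    f$molar_mass <- infer_molar_mass(f, r$vm, cell_volume = r$V_printed)
    attr(f, "V_printed") <- r$V_printed
    attr(f, "vm_printed") <- r$vm
    f
  })
  if (n_random > 0) {
    extra <- .with_seed(seed, lapply(seq_len(n_random), function(i) {
      crystal_form(sprintf("random %d", i),
                   unit_cell(stats::runif(1, 20, 80),
                             stats::runif(1, 20, 80),
                             stats::runif(1, 20, 80)),
                   space_group(sample(c("P1", "P21", "P212121"), 1)),
                   copies_per_asu = sample(1:2, 1),
                   molar_mass = stats::runif(1, 10e3, 20e3))
    }))
    forms <- c(forms, extra)
  }
  forms
}

# convex-polygon templates of unit area, vertices counter-clockwise
.shape_template <- function(shape) {
  if (shape == "lamella") {
    # regular hexagon, area (3*sqrt(3)/2) R^2
    R <- sqrt(2 / (3 * sqrt(3)))
    th <- pi / 6 + (0:5) * pi / 3
    cbind(R * cos(th), R * sin(th))
  } else {
    # elongated 3:1 rectangle (prismatic habit seen side-on)
    w <- sqrt(1 / 3)
    cbind(c(-1.5, 1.5, 1.5, -1.5) * w, c(-0.5, -0.5, 0.5, 0.5) * w)
  }
}

# analytic soft-edge coverage of a convex polygon over a pixel grid:
# signed distance is the max over edge half-planes; coverage ramps
# linearly across one pixel
.render_polygon <- function(verts, nx, ny, cx, cy, soft = 0.75) {
  xs <- matrix(rep(seq_len(nx) - 0.5 - cx, ny), nx, ny)
  ys <- matrix(rep(seq_len(ny) - 0.5 - cy, each = nx), nx, ny)
  nv <- nrow(verts)
  d <- matrix(-Inf, nx, ny)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ex <- verts[j, 1] - verts[i, 1]; ey <- verts[j, 2] - verts[i, 2]
    len <- sqrt(ex^2 + ey^2)
    nrm <- c(ey, -ex) / len               # outward for CCW vertices
    di <- nrm[1] * (xs - verts[i, 1]) + nrm[2] * (ys - verts[i, 2])
    d <- pmax(d, di)
  }
  pmin(1, pmax(0, 0.5 - d / soft))
}

#' Generate a dissolving-crystal image stack with ground truth
#'
#' Renders a convex crystal silhouette (regular hexagon for the lamellar
#' habit, elongated rectangle for the prismatic habit) whose projected area
#' follows the requested dissolution law, as dark-on-bright bright-field
#' frames at fixed intervals with soft sub-pixel edges and additive
#' Gaussian noise.
#'
#' Laws: `"linear"` shrinks the area linearly to zero over `t_dissolve_min`
#' minutes; `"pk_profile"` follows the lamellar sink-dissolution mass
#' fraction `M(t)/M0 = exp(-t/tau)` of the depot model (projected area is
#' proportional to mass for a constant-thickness lamella).
#'
#' @param law `"linear"` or `"pk_profile"`.
#' @param shape `"lamella"` or `"prism"`.
#' @param n_frames Number of frames (default 13).
#' @param dt_min Frame interval, minutes (default 2, the imaging cadence).
#' @param t_dissolve_min Linear law: time of complete dissolution (default
#'   20 min).
#' @param tau_min pk law: exponential time constant (default 6 min).
#' @param area0_um2 Initial projected area, square micrometres (default
#'   2000).
#' @param pixel_size Pixel edge, micrometres (default 0.5).
#' @param img_px Square frame edge, pixels (default 192).
#' @param noise_level Additive Gaussian noise SD as a fraction of the
#'   crystal/background contrast (default 0.05).
#' @param angle_deg In-plane orientation of the crystal, degrees (default
#'   17; crystals settle at arbitrary orientations, and a non-axis-aligned
#'   silhouette also avoids coherent rasterization error along straight
#'   edges).
#' @param seed RNG seed (noise reproducibility).
#' @param label Stack label.
#' @return List with `stack` (an [image_stack()]) and `truth` (data.frame
#'   `t, area, percent_remaining` of exact polygon areas).
#' @export
make_dissolution_stack <- function(law = c("linear", "pk_profile"),
                                   shape = c("lamella", "prism"),
                                   n_frames = 13, dt_min = 2,
                                   t_dissolve_min = 20, tau_min = 6,
                                   area0_um2 = 2000, pixel_size = 0.5,
                                   img_px = 192, noise_level = 0.05,
                                   angle_deg = 17, seed = NULL,
                                   label = "synthetic") {
  law <- match.arg(law)
  shape <- match.arg(shape)
  t_min <- dt_min * (seq_len(n_frames) - 1)
  frac <- switch(law,
    linear = pmax(0, 1 - t_min / t_dissolve_min),
    pk_profile = exp(-t_min / tau_min))
  clipped <- law == "linear" && any(1 - t_min / t_dissolve_min < 0)
  areas <- frac * area0_um2
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  template <- .shape_template(shape) %*% t(rot)
  bg <- 0.85; contrast <- 0.6
  rendered_px <- numeric(n_frames)
  frames <- .with_seed(seed, lapply(seq_len(n_frames), function(i) {
    px_area <- areas[[i]] / pixel_size^2
    cov <- if (px_area > 0)
      .render_polygon(template * sqrt(px_area), img_px, img_px,
                      img_px / 2, img_px / 2)
    else matrix(0, img_px, img_px)
    rendered_px[[i]] <<- sum(cov)
    img <- bg - contrast * cov +
      stats::rnorm(img_px * img_px, 0, noise_level * contrast)
    xtal_frame(matrix(pmin(1, pmax(0, img)), img_px, img_px),
               pixel_size, t_min[[i]])
  }))
  truth <- data.frame(t = t_min, area = areas,
                      percent_remaining = 100 * frac,
                      rendered_area_px = rendered_px)
  structure(list(stack = image_stack(frames, label), truth = truth),
            clipped = clipped)
}

#' Generate a two-event thermogram
#'
#' Two Gaussian unfolding peaks on a linear baseline over the 15-100 C
#' scan range, with additive Gaussian noise.
#'
#' @param Tm1,Tm2 Peak temperatures, C, `15 < Tm1 < Tm2 < 100`.
#' @param widths Gaussian SDs of the two peaks, C (default `c(2.5, 3)`).
#' @param heights Peak heights (default `c(1, 0.8)`).
#' @param baseline Intercept and slope of the linear baseline
#'   (default `c(0.1, 0.002)`).
#' @param noise Additive noise SD as a fraction of the taller peak
#'   (default 0.02).
#' @param step Temperature step, C (default 0.1).
#' @param seed RNG seed.
#' @return A [thermogram()]; peaks closer than 3 C (the detector limit) are
#'   flagged with a warning.
#' @export
make_thermogram <- function(Tm1 = 55, Tm2 = 63, widths = c(2.5, 3),
                            heights = c(1, 0.8), baseline = c(0.1, 0.002),
                            noise = 0.02, step = 0.1, seed = NULL) {
  if (!(Tm1 > 15 && Tm2 < 100 && Tm1 < Tm2))
    stop("need 15 < Tm1 < Tm2 < 100", call. = FALSE)
  if (Tm2 - Tm1 < 3)
    warning("peaks closer than 3 C: below the detector separation limit")
  Tg <- seq(15, 100, by = step)
  y <- baseline[[1]] + baseline[[2]] * Tg +
    heights[[1]] * exp(-(Tg - Tm1)^2 / (2 * widths[[1]]^2)) +
    heights[[2]] * exp(-(Tg - Tm2)^2 / (2 * widths[[2]]^2))
  y <- y + .with_seed(seed,
    stats::rnorm(length(Tg), 0, noise * max(heights)))
  thermogram(Tg, y)
}

#' Generate a static-light-scattering trace
#'
#' Flat baseline followed by a logistic-shaped rise departing from the
#' baseline exactly at `Tagg`, over the 15-95 C scan range.
#'
#' @param Tagg Aggregation onset, C in (15, 95), or `NA` for a flat trace.
#' @param steepness Rise scale, C (default 0.8).
#' @param amplitude Saturating rise amplitude (default 1).
#' @param baseline Baseline level (default 0.05).
#' @param wavelength 266 or 473 nm.
#' @param noise Additive noise SD as a fraction of `amplitude`
#'   (default 0.02).
#' @param step Temperature step, C (default 0.2).
#' @param seed RNG seed.
#' @return An [sls_trace()].
#' @export
make_sls_trace <- function(Tagg = 45, steepness = 0.8, amplitude = 1,
                           baseline = 0.05, wavelength = 266,
                           noise = 0.02, step = 0.2, seed = NULL) {
  Tg <- seq(15, 95, by = step)
  y <- rep(baseline, length(Tg))
  if (!is.na(Tagg)) {
    if (Tagg <= 15 || Tagg >= 95)
      stop("Tagg must lie in (15, 95)", call. = FALSE)
    x <- (Tg - Tagg) / steepness
    rise <- ifelse(Tg >= Tagg, amplitude * (2 / (1 + exp(-x)) - 1), 0)
    y <- y + rise
  }
  y <- y + .with_seed(seed, stats::rnorm(length(Tg), 0, noise * amplitude))
  sls_trace(Tg, y, wavelength)
}
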