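# Dissolution-elimination pharmacokinetics of a crystalline protein depot in
# the vitreous. The depot dissolves by a Noyes-Whitney surface flux
#   dM/dt  = -A(M) * h * (Cs - Ct)
# while dissolved protein is cleared first-order into the aqueous humor
#   dCt/dt =  A(M) * h * (Cs - Ct) / V - k * Ct.
# The diffusion constant and boundary-layer thickness only ever enter as
# their ratio, merged here into one mass-transfer coefficient h (cm/day).

#' Pharmacokinetic parameters for the vitreous compartment
#'
#' @param k First-order elimination rate, 1/day. Alternatively supply
#'   `t_half_days` and `k` is derived as `log(2)/t_half_days`.
#' @param h Mass-transfer coefficient (diffusion constant over
#'   boundary-layer thickness), cm/day.
#' @param V Intravitreal aqueous volume, mL.
#' @param Cs Equilibrium solubility of the crystal lattice, mg/mL.
#' @param C_threshold Minimum efficacious concentration, mg/mL.
#' @param t_half_days Optional elimination half-life, days; used when `k` is
#'   missing. The human vitreous half-life of therapeutic proteins is about
#'   8-11 days; 9.5 days is the midpoint default used in the shipped config.
#' @return Object of class `pk_parameters`.
#' @export
pk_parameters <- function(k = NULL, h = 1, V = 4.5, Cs = 1,
                          C_threshold = 0.01, t_half_days = NULL) {
  if (is.null(k)) {
    if (is.null(t_half_days))
      stop("supply either k or t_half_days", call. = FALSE)
    k <- log(2) / t_half_days
  }
  if (!is.finite(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (h <= 0) stop("h must be positive", call. = FALSE)
  if (V <= 0) stop("V must be positive", call. = FALSE)
  if (Cs < 0) stop("Cs must be non-negative", call. = FALSE)
  if (C_threshold < 0) stop("C_threshold must be non-negative",
                            call. = FALSE)
  structure(list(k = k, h = h, V = V, Cs = Cs, C_threshold = C_threshold),
            class = "pk_parameters")
}

#' Crystalline depot geometry
#'
#' Total dissolving surface area is tied to remaining mass by
#' \eqn{A(M) = A_0 (M/M_0)^p} with p = 2/3 for isometric (prismatic)
#' crystals shrinking self-similarly and p = 1 for lamellar crystals of
#' constant thickness shrinking in-plane.
#'
#' @param M0 Initial crystal mass, mg (> 0).
#' @param A0 Initial total crystal surface area, cm^2 (> 0).
#' @param geometry `"isometric"` (p = 2/3) or `"lamellar"` (p = 1).
#' @return Object of class `crystal_depot` with the shape exponent `p`.
#' @export
crystal_depot <- function(M0, A0, geometry = c("lamellar", "isometric")) {
  geometry <- match.arg(geometry)
  if (M0 <= 0 || A0 <= 0) stop("M0 and A0 must be positive", call. = FALSE)
  structure(list(M0 = M0, A0 = A0, geometry = geometry,
                 p = if (geometry == "lamellar") 1 else 2 / 3),
            class = "crystal_depot")
}

#' Zinc-dependent lattice solubility
#'
#' Zinc coordination in the crystal lattice suppresses the equilibrium
#' solubility. The suppression is modelled with the simplest bounded,
#' strictly decreasing form, a saturable hyperbola
#' \eqn{C_s(zn) = C_{s0} K / (K + zn)}.
#'
#' @param Cs0 Solubility at zero zinc, mg/mL (> 0).
#' @param K_zn Half-suppression zinc concentration, mM (> 0).
#' @return Object of class `zinc_solubility`.
#' @export
zinc_solubility <- function(Cs0, K_zn) {
  if (Cs0 <= 0 || K_zn <= 0) stop("Cs0 and K_zn must be positive",
                                  call. = FALSE)
  structure(list(Cs0 = Cs0, K_zn = K_zn), class = "zinc_solubility")
}

#' Solubility at a given zinc concentration
#'
#' @param model A [zinc_solubility()] model.
#' @param zn Zinc concentration, mM (>= 0).
#' @return Adjusted solubility, mg/mL; `Cs(0) = Cs0`, strictly decreasing.
#' @export
zinc_adjusted_solubility <- function(model, zn) {
  if (any(zn < 0)) stop("zn must be non-negative", call. = FALSE)
  model$Cs0 * model$K_zn / (model$K_zn + zn)
}

.conc_profile <- function(t, Ct, M, eliminated, params, M0, C0) {
  structure(data.frame(t = t, Ct = Ct, M = M, eliminated = eliminated),
            class = c("conc_profile", "data.frame"),
            params = params, M0 = M0, C0 = C0)
}

#' Bolus reference profile (closed form)
#'
#' Intravitreal concentration after a solution bolus under first-order
#' elimination: \eqn{C(t) = C_0 e^{-kt}}. Evaluated in closed form, no
#' solver.
#'
#' @param C0 Initial concentration, mg/mL (>= 0).
#' @param params [pk_parameters()].
#' @param t_grid Time grid, days, non-decreasing from 0.
#' @return A `conc_profile` data.frame with columns `t, Ct, M, eliminated`
#'   (`M` is 0 throughout; `eliminated` is the cleared mass `C0*V*(1-e^-kt)`).
#' @export
simulate_bolus <- function(C0, params, t_grid) {
  if (C0 < 0) stop("C0 must be non-negative", call. = FALSE)
  Ct <- C0 * exp(-params$k * t_grid)
  .conc_profile(t_grid, Ct, M = 0 * t_grid,
                eliminated = C0 * params$V * (1 - exp(-params$k * t_grid)),
                params = params, M0 = 0, C0 = C0)
}

# right-hand side of the depot ODE; state y = (M, Ct, eliminated mass)
.depot_rhs <- function(t, y, p) {
  m <- max(y[[1]], 0)
  A <- if (m == 0) 0 else p$A0 * (m / p$M0)^p$pexp
  flux <- A * p$h * (p$Cs - y[[2]])          # mg/day dissolved
  list(c(-flux, flux / p$V - p$k * y[[2]], p$k * y[[2]] * p$V))
}

#' Simulate a crystalline depot in the vitreous
#'
#' Integrates the coupled dissolution-elimination system with a stiff-safe
#' adaptive solver (deSolve `lsodar`, relative tolerance 1e-8 by default).
#' Dissolution halts exactly when the depot is exhausted: a root function
#' detects M = 0 and an event pins the state there rather than clipping.
#'
#' @param depot [crystal_depot()].
#' @param params [pk_parameters()].
#' @param t_grid Strictly increasing time grid starting at 0, days.
#' @param zinc Optional zinc concentration, mM; requires `zinc_model`.
#' @param zinc_model Optional [zinc_solubility()]; when given together with
#'   `zinc`, the lattice solubility `Cs` is first mapped through it.
#' @param C0 Initial dissolved concentration, mg/mL (default 0).
#' @param rtol,atol Solver tolerances.
#' @return A `conc_profile` data.frame (`t, Ct, M, eliminated`) whose mass
#'   balance `M + Ct*V + eliminated = M0 + C0*V` holds to solver tolerance.
#'   Attribute `t_exhausted` carries the depot-exhaustion time (NA if the
#'   depot outlives the grid).
#' @export
simulate_crystal_depot <- function(depot, params, t_grid, zinc = NULL,
                                   zinc_model = NULL, C0 = 0,
                                   rtol = 1e-8, atol = NULL) {
  if (length(t_grid) < 2 || t_grid[[1]] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing from 0", call. = FALSE)
  Cs <- params$Cs
  if (!is.null(zinc)) {
    if (is.null(zinc_model))
      stop("zinc given without a zinc_solubility model", call. = FALSE)
    Cs <- zinc_adjusted_solubility(zinc_model, zinc)
  }
  p <- list(A0 = depot$A0, M0 = depot$M0, pexp = depot$p,
            h = params$h, Cs = Cs, V = params$V, k = params$k)
  if (is.null(atol)) atol <- 1e-10 * max(depot$M0, 1)
  y0 <- c(M = depot$M0, Ct = C0, elim = 0)
  # root 1: exhaustion (event pins M to 0); isometric depots reach it in
  # finite time, lamellar ones asymptotically -- the tiny floor makes the
  # event well-defined for both.
  rootfun <- function(t, y, p) y[[1]] - 1e-9 * p$M0
  eventfun <- function(t, y, p) { y[[1]] <- 0; y }
  out <- deSolve::lsodar(y0, t_grid, .depot_rhs, parms = p,
                         rtol = rtol, atol = atol, rootfunc = rootfun,
                         events = list(func = eventfun, root = TRUE))
  if (attr(out, "istate")[[1]] < 0)
    stop("depot integration failed to meet tolerance (istate = ",
         attr(out, "istate")[[1]], ")", call. = FALSE)
  troot <- attr(out, "troot")
  prof <- .conc_profile(out[, "time"], pmax(out[, "Ct"], 0),
                        pmax(out[, "M"], 0), out[, "elim"],
                        params = params, M0 = depot$M0, C0 = C0)
  attr(prof, "Cs_effective") <- Cs
  attr(prof, "t_exhausted") <- if (length(troot)) troot[[1]] else NA_real_
  prof
}

#' Time above an efficacy threshold
#'
#' Total measure of the set `{t : Ct(t) >= threshold}`, by linear
#' interpolation of the concentration between grid points.
#'
#' @param profile A `conc_profile`.
#' @param threshold Threshold concentration, mg/mL (> 0).
#' @return Time above threshold in the profile's time unit (days). 0 when
#'   the profile never reaches the threshold.
#' @export
time_above_threshold <- function(profile, threshold) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  t <- profile$t; y <- profile$Ct - threshold
  tot <- 0
  for (i in seq_len(length(t) - 1)) {
    y0 <- y[[i]]; y1 <- y[[i + 1]]; dt <- t[[i + 1]] - t[[i]]
    if (y0 >= 0 && y1 >= 0) tot <- tot + dt
    else if (y0 > 0 && y1 < 0) tot <- tot + dt * y0 / (y0 - y1)
    else if (y0 < 0 && y1 > 0) tot <- tot + dt * y1 / (y1 - y0)
  }
  tot
}

#' Injection-interval extension on dose doubling (bolus)
#'
#' For a solution bolus under first-order elimination, doubling the dose
#' extends the time above any efficacy threshold by exactly one elimination
#' half-life: `t(2*C0) - t(C0) = log(2)/k`, independent of dose and
#' threshold. Computed from the closed-form crossing times
#' `log(C0/threshold)/k`.
#'
#' @param params [pk_parameters()] (its `C_threshold` is used).
#' @param C0 Initial bolus concentration, mg/mL; must exceed the threshold.
#' @return Extension in days (= one half-life).
#' @export
interval_extension_on_dose_doubling <- function(params, C0) {
  thr <- params$C_threshold
  if (thr <= 0) stop("params$C_threshold must be positive", call. = FALSE)
  if (C0 <= thr) stop("C0 must exceed the efficacy threshold", call. = FALSE)
  log(2 * C0 / thr) / params$k - log(C0 / thr) / params$k
}

#' Complete-dissolution time of a depot
#'
#' Time at which the remaining crystal mass first falls below
#' `floor_frac * M0` (default 1e-6). Under sink conditions (`sink = TRUE`,
#' the large-volume release-medium approximation where the bulk
#' concentration is held at zero) the closed forms are used:
#' lamellar (p = 1) mass decays exponentially with time constant
#' `tau = M0/(A0*h*Cs)`, so `t = tau * log(1/floor_frac)`; isometric
#' (p = 2/3) reaches the floor at `3*tau*(1 - floor_frac^(1/3))`. With a
#' finite release volume the full system is integrated and the root time of
#' the mass floor is reported.
#'
#' @param depot [crystal_depot()].
#' @param params [pk_parameters()]; `Cs` must be positive (possibly after
#'   zinc adjustment).
#' @param zinc,zinc_model Optional zinc adjustment as in
#'   [simulate_crystal_depot()].
#' @param sink Hold the bulk concentration at zero (default TRUE, matching a
#'   drop assay read against a large reservoir).
#' @param t_max Horizon for the finite-volume search, days.
#' @param floor_frac Mass floor defining "completely dissolved".
#' @return List with `time` (days) and `censored` (TRUE when the floor was
#'   not reached within `t_max`; `time` is then `t_max`).
#' @export
complete_dissolution_time <- function(depot, params, zinc = NULL,
                                      zinc_model = NULL, sink = TRUE,
                                      t_max = 365, floor_frac = 1e-6) {
  Cs <- params$Cs
  if (!is.null(zinc)) {
    if (is.null(zinc_model))
      stop("zinc given without a zinc_solubility model", call. = FALSE)
    Cs <- zinc_adjusted_solubility(zinc_model, zinc)
  }
  if (Cs <= 0) stop("effective Cs must be positive", call. = FALSE)
  if (sink) {
    tau <- depot$M0 / (depot$A0 * params$h * Cs)
    tm <- if (depot$p == 1) tau * log(1 / floor_frac)
          else 3 * tau * (1 - floor_frac^(1 / 3))
    return(list(time = tm, censored = FALSE))
  }
  p <- list(A0 = depot$A0, M0 = depot$M0, pexp = depot$p,
            h = params$h, Cs = Cs, V = params$V, k = params$k)
  rootfun <- function(t, y, p) y[[1]] - floor_frac * p$M0
  out <- deSolve::lsodar(c(M = depot$M0, Ct = 0, elim = 0),
                         seq(0, t_max, length.out = 200), .depot_rhs,
                         parms = p, rtol = 1e-8,
                         atol = 1e-12 * depot$M0, rootfunc = rootfun)
  troot <- attr(out, "troot")
  if (length(troot)) list(time = troot[[1]], censored = FALSE)
  else list(time = t_max, censored = TRUE)
}

#' Refit solubility and mass-transfer coefficient from a profile
#'
#' Least-squares recovery of `(Cs, h)` from an observed concentration
#' profile, holding the depot geometry and the elimination parameters fixed.
#' Uses Levenberg-Marquardt on log-parameters (both are positive scale
#' parameters).
#'
#' @param profile A `conc_profile` (possibly noisy) with columns `t, Ct`.
#' @param depot [crystal_depot()] used to generate the data.
#' @param params [pk_parameters()] supplying the known `k` and `V`; its `Cs`
#'   and `h` are ignored.
#' @param start Optional named vector `c(Cs =, h =)` of starting values;
#'   defaults are derived from the profile (twice the peak concentration,
#'   and the initial rise slope).
#' @return Named vector `c(Cs, h)` of fitted values.
#' @export
fit_dissolution_params <- function(profile, depot, params, start = NULL) {
  t_grid <- profile$t
  obs <- profile$Ct
  if (is.null(start)) {
    Cs0 <- 2 * max(obs)
    i2 <- max(2, which.max(obs > 0.05 * max(obs)))
    slope0 <- max(obs[[i2]] / t_grid[[i2]], .Machine$double.eps)
    h0 <- slope0 * params$V / (depot$A0 * Cs0)
    start <- c(Cs = Cs0, h = h0)
  }
  resid_fn <- function(logpar) {
    pr <- pk_parameters(k = params$k, h = exp(logpar[[2]]), V = params$V,
                        Cs = exp(logpar[[1]]),
                        C_threshold = params$C_threshold)
    sim <- simulate_crystal_depot(depot, pr, t_grid)
    sim$Ct - obs
  }
  fit <- minpack.lm::nls.lm(par = log(start), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- exp(fit$par)
  names(est) <- c("Cs", "h")
  est
}

#' Read a PK scenario configuration
#'
#' JSON or YAML (detected by extension) with blocks
#' `pk: {k | t_half_days, h, V_ml, Cs, threshold}`,
#' `depot: {M0_mg, A0_cm2, geometry}`, optional
#' `zinc: {Cs0, K_zn, zn_mM}`, and `t_end_days, n_points, seed`.
#'
#' @param path Config file path.
#' @return List with `params`, `depot`, `zinc_model`, `zn_mM`, `t_grid`,
#'   `seed`.
#' @export
read_pk_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  pk <- cfg$pk
  `%||%` <- function(x, y) if (is.null(x)) y else x
  params <- pk_parameters(k = pk$k, h = pk$h %||% 1,
                          V = pk$V_ml %||% 4.5, Cs = pk$Cs %||% 1,
                          C_threshold = pk$threshold %||% 0.01,
                          t_half_days = pk$t_half_days)
  depot <- crystal_depot(cfg$depot$M0_mg, cfg$depot$A0_cm2,
                         cfg$depot$geometry)
  zm <- NULL; zn <- NULL
  if (!is.null(cfg$zinc)) {
    zm <- zinc_solubility(cfg$zinc$Cs0, cfg$zinc$K_zn)
    zn <- cfg$zinc$zn_mM
  }
  t_end <- if (is.null(cfg$t_end_days)) 60 else cfg$t_end_days
  n <- if (is.null(cfg$n_points)) 601 else cfg$n_points
  list(params = params, depot = depot, zinc_model = zm, zn_mM = zn,
       t_grid = seq(0, t_end, length.out = n),
       seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed)
}

#' Write a concentration profile and summary
#'
#' Writes the tidy CSV `t_days,Ct,M,eliminated` and a JSON summary with the
#' time above threshold, depot-exhaustion time and peak concentration.
#'
#' @param profile A `conc_profile`.
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @param threshold Efficacy threshold for the summary; defaults to the
#'   profile's stored `C_threshold`.
#' @return The summary list, invisibly.
#' @export
write_profile <- function(profile, csv_path = NULL, json_path = NULL,
                          threshold = NULL) {
  if (is.null(threshold))
    threshold <- attr(profile, "params")$C_threshold
  if (!is.null(csv_path)) {
    df <- data.frame(t_days = profile$t, Ct = profile$Ct, M = profile$M,
                     eliminated = profile$eliminated)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  summary <- list(
    time_above_threshold = time_above_threshold(profile, threshold),
    t_exhausted = attr(profile, "t_exhausted"),
    peak_Ct = max(profile$Ct)
  )
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(summary)
}
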