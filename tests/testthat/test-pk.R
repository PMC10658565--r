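test_that("bolus profile is the first-order closed form", {
  p <- pk_parameters(t_half_days = 9.5, C_threshold = 0.01)
  tg <- seq(0, 60, by = 0.1)
  prof <- simulate_bolus(1, p, tg)
  expect_equal(prof$Ct[[1]], 1)
  expect_equal(prof$Ct, exp(-p$k * tg))
  # half-life definition
  half <- simulate_bolus(1, p, c(0, log(2) / p$k))
  expect_equal(half$Ct[[2]], 0.5, tolerance = 1e-12)
  expect_error(pk_parameters(k = -1), "positive")
})

test_that("time above threshold uses linear interpolation and refines stably", {
  p <- pk_parameters(t_half_days = 9.5, C_threshold = 0.01)
  tg <- seq(0, 120, by = 0.5)
  prof <- simulate_bolus(2 * 0.01, p, tg)
  # closed form: ln2/k for a dose at twice the threshold
  expect_equal(time_above_threshold(prof, 0.01), log(2) / p$k,
               tolerance = 1e-3)
  # boundary: threshold at C0 counts only the instant
  expect_equal(time_above_threshold(prof, 2 * 0.01), 0)
  # threshold above the peak returns 0, not an error
  expect_equal(time_above_threshold(prof, 1), 0)
  # invariant to 10x grid refinement within 1%
  fine <- simulate_bolus(2 * 0.01, p, seq(0, 120, by = 0.05))
  expect_equal(time_above_threshold(prof, 0.01),
               time_above_threshold(fine, 0.01), tolerance = 0.01)
})

test_that("dose doubling extends the interval by exactly one half-life", {
  for (th in c(8, 9.5, 11)) {
    p <- pk_parameters(t_half_days = th, C_threshold = 0.05)
    ext <- vapply(c(2, 5, 50) * p$C_threshold, function(C0)
      interval_extension_on_dose_doubling(p, C0), numeric(1))
    expect_equal(ext, rep(th, 3), tolerance = 1e-12)
  }
  p <- pk_parameters(t_half_days = 9.5, C_threshold = 0.05)
  expect_error(interval_extension_on_dose_doubling(p, 0.01), "exceed")
})

test_that("depot simulation conserves mass and respects saturation", {
  sc <- recovery_scenario()
  prof <- simulate_crystal_depot(sc$depot, sc$params, sc$t_grid)
  mb <- abs(prof$M + prof$Ct * sc$params$V + prof$eliminated -
            sc$depot$M0) / sc$depot$M0
  expect_lt(max(mb), 1e-6)
  expect_true(all(diff(prof$M) <= 1e-12))          # non-increasing mass
  expect_true(all(prof$Ct <= sc$params$Cs + 1e-12)) # never above Cs
  expect_true(all(prof$Ct >= 0))
})

test_that("zero solubility means no dissolution", {
  p <- pk_parameters(t_half_days = 9.5, h = 1, Cs = 0)
  d <- crystal_depot(5, 2, "lamellar")
  prof <- simulate_crystal_depot(d, p, seq(0, 30, length.out = 61))
  expect_equal(prof$Ct, rep(0, 61))
  expect_equal(prof$M, rep(5, 61))
})

test_that("fast transfer with a small dose converges to the bolus", {
  p <- pk_parameters(t_half_days = 9.5, h = 2000, V = 4.5, Cs = 10,
                     C_threshold = 0.01)
  d <- crystal_depot(M0 = 1, A0 = 1, "lamellar")
  tg <- seq(0, 30, by = 0.05)
  depot <- simulate_crystal_depot(d, p, tg)
  bolus <- simulate_bolus(d$M0 / p$V, p, tg)
  # sup-norm gap after the (instantaneous) dissolution transient
  gap <- max(abs(depot$Ct[-1] - bolus$Ct[-1]))
  expect_lt(gap, 0.01 * max(bolus$Ct))
})

test_that("inexhaustible depot reaches the algebraic steady state", {
  p <- pk_parameters(k = 0.073, h = 0.05, V = 4.5, Cs = 1)
  d <- crystal_depot(M0 = 1e9, A0 = 10, "lamellar")
  prof <- simulate_crystal_depot(d, p, seq(0, 400, length.out = 201))
  ah_v <- d$A0 * p$h / p$V
  expect_equal(prof$Ct[[201]], p$Cs * ah_v / (ah_v + p$k),
               tolerance = 1e-6)
})

test_that("crystal depot outlasts an equal-dose bolus above threshold", {
  # half-life 9.5 d, lamellar depot with solubility low enough that
  # dissolution persists for weeks
  p <- pk_parameters(t_half_days = 9.5, h = 0.05, V = 4.5, Cs = 0.2,
                     C_threshold = 0.02)
  d <- crystal_depot(M0 = 10, A0 = 10, "lamellar")
  tg <- seq(0, 240, length.out = 961)
  depot <- simulate_crystal_depot(d, p, tg)
  bolus <- simulate_bolus(d$M0 / p$V, p, tg)
  expect_gt(time_above_threshold(depot, p$C_threshold),
            time_above_threshold(bolus, p$C_threshold))
})

test_that("zinc solubility model is hyperbolic and strictly decreasing", {
  zm <- zinc_solubility(Cs0 = 0.5, K_zn = 100)
  expect_equal(zinc_adjusted_solubility(zm, 0), 0.5)
  expect_equal(zinc_adjusted_solubility(zm, 100), 0.25)
  zn <- seq(0, 300, by = 10)
  cs <- zinc_adjusted_solubility(zm, zn)
  expect_true(all(diff(cs) < 0))
  expect_error(zinc_adjusted_solubility(zm, -1), "non-negative")
})

test_that("complete dissolution time scales with mass and solubility", {
  p <- pk_parameters(t_half_days = 9.5, h = 0.05, Cs = 0.5)
  d1 <- crystal_depot(M0 = 5, A0 = 10, "lamellar")
  d2 <- crystal_depot(M0 = 10, A0 = 10, "lamellar")
  t1 <- complete_dissolution_time(d1, p, sink = TRUE)
  t2 <- complete_dissolution_time(d2, p, sink = TRUE)
  expect_false(t1$censored)
  expect_equal(t2$time / t1$time, 2, tolerance = 1e-12)
  # halving Cs strictly increases the time (sink and finite-volume modes)
  p_half <- pk_parameters(t_half_days = 9.5, h = 0.05, Cs = 0.25)
  expect_gt(complete_dissolution_time(d1, p_half, sink = TRUE)$time,
            t1$time)
  tf <- complete_dissolution_time(d1, p, sink = FALSE, t_max = 2000)
  tf_half <- complete_dissolution_time(d1, p_half, sink = FALSE,
                                       t_max = 2000)
  expect_gt(tf_half$time, tf$time)
  # censoring is flagged, not an error
  slow <- pk_parameters(t_half_days = 9.5, h = 1e-6, Cs = 0.01)
  cens <- complete_dissolution_time(d1, slow, sink = FALSE, t_max = 10)
  expect_true(cens$censored)
})

test_that("geometry mode changes the exhaustion profile as the area law dictates", {
  # under A(M) = A0 (M/M0)^p the isometric depot (p = 2/3) keeps the larger
  # relative area as M falls and so completes before the lamellar one
  p <- pk_parameters(t_half_days = 9.5, h = 0.05, Cs = 0.5)
  iso <- crystal_depot(M0 = 5, A0 = 10, "isometric")
  lam <- crystal_depot(M0 = 5, A0 = 10, "lamellar")
  t_iso <- complete_dissolution_time(iso, p, sink = TRUE)$time
  t_lam <- complete_dissolution_time(lam, p, sink = TRUE)$time
  expect_lt(t_iso, t_lam)
  tau <- iso$M0 / (iso$A0 * p$h * p$Cs)
  expect_equal(t_iso, 3 * tau * (1 - 1e-2), tolerance = 1e-12)
  expect_equal(t_lam, tau * log(1e6), tolerance = 1e-12)
})

test_that("dissolution time increases strictly along the zinc gradient", {
  zm <- zinc_solubility(Cs0 = 0.5, K_zn = 100)
  p <- pk_parameters(t_half_days = 9.5, h = 0.05, Cs = 0.5)
  d <- crystal_depot(M0 = 2, A0 = 5, "isometric")
  zn_grid <- c(20, 60, 100, 150, 200, 250, 300)
  times <- vapply(zn_grid, function(zn)
    complete_dissolution_time(d, p, zinc = zn, zinc_model = zm,
                              sink = TRUE)$time, numeric(1))
  expect_true(all(diff(times) > 0))
  # and in the finite-volume release mode as well
  times_fv <- vapply(zn_grid, function(zn)
    complete_dissolution_time(d, p, zinc = zn, zinc_model = zm,
                              sink = FALSE, t_max = 5000)$time, numeric(1))
  expect_true(all(diff(times_fv) > 0))
})

test_that("solubility and transfer coefficient are recoverable from profiles", {
  sc <- recovery_scenario()
  prof <- simulate_crystal_depot(sc$depot, sc$params, sc$t_grid)
  est <- fit_dissolution_params(prof, sc$depot, sc$params)
  expect_equal(unname(est[["Cs"]]), sc$params$Cs, tolerance = 0.01)
  expect_equal(unname(est[["h"]]), sc$params$h, tolerance = 0.01)
  set.seed(7)
  noisy <- prof
  noisy$Ct <- prof$Ct * (1 + 0.05 * rnorm(length(prof$Ct)))
  est2 <- fit_dissolution_params(noisy, sc$depot, sc$params)
  expect_equal(unname(est2[["Cs"]]), sc$params$Cs, tolerance = 0.1)
  expect_equal(unname(est2[["h"]]), sc$params$h, tolerance = 0.1)
})

test_that("scenario configs round-trip through JSON and YAML", {
  cfg <- list(pk = list(t_half_days = 9.5, h = 0.05, V_ml = 4.5, Cs = 0.2,
                        threshold = 0.02),
              depot = list(M0_mg = 10, A0_cm2 = 10, geometry = "lamellar"),
              zinc = list(Cs0 = 0.2, K_zn = 100, zn_mM = 60),
              t_end_days = 90, n_points = 181, seed = 1)
  jp <- withr::local_tempfile(fileext = ".json")
  yp <- withr::local_tempfile(fileext = ".yaml")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE)
  yaml::write_yaml(cfg, yp)
  for (path in c(jp, yp)) {
    sc <- read_pk_config(path)
    expect_equal(sc$params$k, log(2) / 9.5)
    expect_equal(sc$depot$p, 1)
    expect_equal(sc$zn_mM, 60)
    expect_equal(range(sc$t_grid), c(0, 90))
  }
})
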