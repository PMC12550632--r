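# Rupture simulator: Poisson bond counts, the exact-inversion Bell engine
# against analytic oracles, full-trial structure, determinism, calibration.

test_that("bond counts are Poisson with the requested mean", {
  expect_true(all(sample_bond_counts(0, 100, seed = 1) == 0))
  x <- sample_bond_counts(1, 1e5, seed = 2)
  p0 <- mean(x == 0)
  expect_lt(abs(p0 - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / 1e5))
  expect_lt(abs(mean(x) - 1), 3 * sqrt(1 / 1e5))
  expect_error(sample_bond_counts(-1, 10), ">= 0")
})

test_that("a single bond at constant force ruptures exponentially", {
  seg <- data.frame(t0 = 0, t1 = 1e5, f0 = 0, rate = 0)
  m <- bond_model(lam = 1, k0 = 0.05, f_beta = 10)
  tms <- withr::with_seed(3, replicate(
    1, cellavidity:::.rupture_times_bell(rep(1L, 1e4), seg, 0.05, 10)))
  expect_lt(abs(mean(tms) - 1 / 0.05), 3 * (1 / 0.05) / sqrt(1e4))
})

test_that("single-bond rupture forces under a ramp match the Bell closed form", {
  k0 <- 1e-5; fb <- 10; rate <- 4
  seg <- data.frame(t0 = 0, t1 = 150, f0 = 0, rate = rate)
  tms <- withr::with_seed(7, cellavidity:::.rupture_times_bell(
    rep(1L, 1e5), seg, k0, fb))
  forces <- rate * tms[is.finite(tms)]
  expect_gt(length(forces), 0.99e5)
  D <- suppressWarnings(
    ks.test(forces, function(f) bell_ramp_cdf(f, k0, fb, rate))$statistic)
  expect_lt(unname(D), 0.02)
})

test_that("scalar thinning engine agrees with the exact-inversion engine", {
  # custom hazard identical to Bell: the two samplers must agree in law
  k0 <- 0.01; fb <- 12
  m_bell <- bond_model(lam = 1, k0 = k0, f_beta = fb)
  m_thin <- bond_model(lam = 1, k0 = k0, f_beta = fb,
                       hazard = function(f) k0 * exp(f / fb))
  seg <- data.frame(t0 = c(0, 40), t1 = c(40, 120), f0 = c(15, 60),
                    rate = c(0, 0))
  t_thin <- withr::with_seed(11, vapply(
    1:2000, function(i) simulate_cell_rupture(2, m_thin, seg), numeric(1)))
  t_exact <- withr::with_seed(12, cellavidity:::.rupture_times_bell(
    rep(2L, 20000), seg, k0, fb))
  D <- suppressWarnings(ks.test(t_thin[is.finite(t_thin)],
                                t_exact[is.finite(t_exact)])$statistic)
  expect_lt(unname(D), 0.04)
})

test_that("the engine matches the master equation for small bond numbers", {
  skip_if_not_installed("deSolve")
  k0 <- 0.01; fb <- 10
  seg <- data.frame(t0 = c(0, 30), t1 = c(30, 90), f0 = c(20, 60),
                    rate = c(0, 0))
  nb <- 3L
  # master equation for the bond-count ladder under equal load sharing
  rate_b <- function(b, F) b * k0 * exp(F / (b * fb))
  deriv <- function(t, y, parms) {
    F <- if (t < 30) 20 else 60
    dP <- numeric(nb + 1)  # y = (P3, P2, P1, P0)
    for (i in seq_len(nb)) {
      b <- nb - i + 1
      dP[i] <- dP[i] - rate_b(b, F) * y[i]
      dP[i + 1] <- dP[i + 1] + rate_b(b, F) * y[i]
    }
    list(dP)
  }
  # integrate each constant-force piece separately so the force jump at
  # t = 30 s is not smeared by the step controller
  g1 <- seq(0, 30, by = 3)
  g2 <- seq(30, 90, by = 3)
  sol1 <- deSolve::ode(c(1, 0, 0, 0), g1, deriv, NULL)
  sol2 <- deSolve::ode(sol1[nrow(sol1), -1], g2, deriv, NULL)
  grid <- c(g1, g2[-1])
  cdf_model <- c(sol1[, 5], sol2[-1, 5])
  tms <- withr::with_seed(13, cellavidity:::.rupture_times_bell(
    rep(nb, 2e5), seg, k0, fb))
  cdf_emp <- vapply(grid, function(g) mean(tms <= g), numeric(1))
  # L1 distance between the binned rupture-time distributions
  l1 <- sum(abs(diff(cdf_emp) - diff(cdf_model))) +
    abs((1 - max(cdf_emp)) - (1 - max(cdf_model)))
  expect_lt(l1, 0.01)
})

test_that("mean rupture force increases with bond number, roughly linearly", {
  seg <- data.frame(t0 = 0, t1 = 2000, f0 = 0, rate = 4)
  mf <- vapply(c(1L, 2L, 4L, 8L), function(b) {
    tms <- withr::with_seed(100 + b, cellavidity:::.rupture_times_bell(
      rep(b, 3000), seg, 1e-5, 10))
    4 * mean(tms[is.finite(tms)])
  }, numeric(1))
  expect_true(all(diff(mf) > 0))
  # near-linear growth at large n: per-bond increments stabilize
  inc_late <- (mf[4] - mf[3]) / 4
  inc_mid <- (mf[3] - mf[2]) / 2
  expect_gt(inc_late, 0.5 * inc_mid)
  expect_lt(inc_late, 1.5 * inc_mid)
})

test_that("simulated trials have the expected structure and conservation", {
  prot <- assay_protocol(hold = 0)
  tr <- simulate_trial(bond_model(lam = 1), prot, n_cells = 500, seed = 5)
  expect_s3_class(tr$count_trace, "count_trace")
  # counts stay near or below n_cells: symmetric detection noise can
  # overshoot by a few cells per frame, never systematically
  expect_true(all(tr$count_trace$target_count <=
                    500 + 6 * sqrt(2 * 0.02 * 500)))
  expect_lt(mean(head(tr$count_trace$target_count, 20)), 505)
  expect_equal(length(tr$rupture_times), 500)
  # zero-bond cells all leave during the gravity interval
  zero <- tr$bond_counts == 0
  expect_true(all(tr$rupture_times[zero] < 120))
  # noise-free counts are non-increasing
  tr0 <- simulate_trial(bond_model(lam = 1), prot, n_cells = 500,
                        p_miss = 0, seed = 5)
  expect_true(all(diff(tr0$count_trace$target_count) <= 0))
})

test_that("saturating valency yields AF ~ 1 and negligible detachment", {
  prot <- design_ramp(2, f_max = 60, t_start = 120)  # weak, short ramp
  tr <- simulate_trial(bond_model(lam = 20, f_beta = 15), prot,
                       n_cells = 400, seed = 6)
  af <- adhesion_frequency(tr$count_trace)
  expect_gt(af$adhesion_frequency, 0.98)
  cv <- build_detachment_curve(tr$count_trace, "centrifuge_start",
                               t_origin = 120)
  expect_gt(min(cv$fraction_bound), 0.95)
})

test_that("measured adhesion frequency matches 1 - exp(-lambda) across lambdas", {
  prot <- assay_protocol(hold = 0)
  for (lam in c(0.25, 2)) {
    tr <- simulate_trial(bond_model(lam = lam), prot, n_cells = 1000,
                         seed = 50 + round(10 * lam))
    af <- adhesion_frequency(tr$count_trace)$adhesion_frequency
    expected <- af_from_lambda(lam)
    expect_lt(abs(af - expected),
              3 * sqrt(expected * (1 - expected) / 1000))
  }
})

test_that("identical seeds give bit-identical trials", {
  prot <- assay_protocol(hold = 0)
  a <- simulate_trial(bond_model(lam = 1.5), prot, n_cells = 300, seed = 99)
  b <- simulate_trial(bond_model(lam = 1.5), prot, n_cells = 300, seed = 99)
  expect_identical(a$rupture_times, b$rupture_times)
  expect_identical(a$count_trace, b$count_trace)
  c2 <- simulate_trial(bond_model(lam = 1.5), prot, n_cells = 300, seed = 98)
  expect_false(identical(a$count_trace, c2$count_trace))
})

test_that("calibration hits a target slope and responds monotonically to f_beta", {
  prot <- assay_protocol()
  lam_grid <- seq(0.3, 4, length.out = 12)
  k_lo <- cellavidity:::simulate_and_fit_trials(
    lam_grid, bond_model(1, 1e-5, 8), prot, n_cells = 400, seed = 3)$fit$k
  k_hi <- cellavidity:::simulate_and_fit_trials(
    lam_grid, bond_model(1, 1e-5, 16), prot, n_cells = 400, seed = 3)$fit$k
  expect_gt(k_hi, k_lo)
  cal <- calibrate_bond_params(12, protocol = prot, lambdas = lam_grid,
                               n_cells = 400, seed = 3)
  expect_lt(abs(attr(cal, "achieved_k") - 12) / 12, 0.02)
  expect_error(calibrate_bond_params(500, protocol = prot,
                                     lambdas = lam_grid, n_cells = 200,
                                     seed = 3),
               "achievable")
})
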