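# Kinetics: Poisson closure, stretched-exponential fits, universal curve,
# off-rate estimator.

test_that("Poisson closure links lambda and adhesion frequency", {
  expect_equal(af_from_lambda(0), 0)
  expect_equal(af_from_lambda(log(2)), 0.5)
  # cross-check 1 - e^-1 by summing the Poisson pmf over x >= 1
  pmf_sum <- sum(dpois(1:60, 1))
  expect_equal(af_from_lambda(1), pmf_sum, tolerance = 1e-12)
  expect_equal(af_from_lambda(1), 0.63212, tolerance = 1e-5)
  expect_error(af_from_lambda(-0.1), ">= 0")
})

test_that("lambda_from_af inverts the closure and caps at af_cap", {
  expect_equal(lambda_from_af(0), 0)
  a <- c(0.1, 0.5, 0.632, 0.95)
  expect_equal(af_from_lambda(lambda_from_af(a)), a, tolerance = 1e-12)
  expect_equal(lambda_from_af(0.632), 1, tolerance = 0.01)
  expect_equal(lambda_from_af(1), -log(1 - 0.999))
  expect_error(lambda_from_af(1.2), "\\[0, 1\\]")
})

test_that("af_from_lambda is increasing, concave, and asymptotes to 1", {
  lam <- seq(0, 12, by = 0.05)
  af <- af_from_lambda(lam)
  expect_true(all(diff(af) > 0))
  expect_true(all(diff(diff(af)) < 1e-12))
  expect_lt(1 - af_from_lambda(12), 1e-5)
})

test_that("stretched-exponential evaluation hits its boundary values", {
  for (p in list(c(0.3, 10, 0.7), c(0.9, 55, 2.3), c(1, 5, 1))) {
    expect_equal(stretched_exp(0, p[1], p[2], p[3]), 1)
    expect_equal(stretched_exp(1e9, p[1], p[2], p[3]), 1 - p[1],
                 tolerance = 1e-12)
  }
})

test_that("noiseless stretched-exponential curves are recovered to high precision", {
  for (g in c(0.6, 0.95)) for (tau in c(20, 80)) for (beta in c(0.8, 2.5)) {
    fit <- fit_stretched_exponential(se_curve(g, tau, beta))
    expect_true(fit$converged)
    expect_equal(fit$g, g, tolerance = 1e-6)
    expect_equal(fit$tau, tau, tolerance = 1e-6)
    expect_equal(fit$beta, beta, tolerance = 1e-6)
  }
})

test_that("beta fixed near 1 reduces to a simple exponential fit", {
  tt <- seq(0, 200, by = 0.5)
  cv <- data.frame(time_s = tt, fraction_bound = exp(-tt / 35))
  fit <- fit_stretched_exponential(cv)
  expect_equal(fit$tau, 35, tolerance = 1e-4)
  expect_equal(fit$beta, 1, tolerance = 1e-4)
  expect_equal(fit$g, 1, tolerance = 1e-4)
})

test_that("flat curves yield a flagged degenerate fit, not a crash", {
  cv <- data.frame(time_s = seq(0, 100, 1), fraction_bound = rep(1, 101))
  fit <- fit_stretched_exponential(cv)
  expect_false(fit$converged)
  expect_match(fit$flags, "degenerate")
  expect_equal(fit$g, 0)
  expect_error(fit_stretched_exponential(se_curve(0.9, 40, 1.5,
                                                  times = seq(0, 4, 1))),
               "at least 10")
})

test_that("fitted lifetime grows with bond valency under the same ramp", {
  prot <- assay_protocol(hold = 0)
  taus <- sapply(c(1, 2), function(lam) {
    tr <- simulate_trial(bond_model(lam = lam, f_beta = 8), prot,
                         n_cells = 1000, seed = 77)
    cv <- build_detachment_curve(tr$count_trace, "centrifuge_start",
                                 t_origin = 120)
    fit_stretched_exponential(cv)$tau
  })
  expect_gt(taus[2], taus[1])
})

test_that("universal curve recovers exact parameters from points on the curve", {
  lam <- seq(0.2, 5, length.out = 12)
  pts <- trial_points(af_from_lambda(lam), 15.4 * lam + 3.5)
  fit <- fit_universal_curve(pts)
  expect_equal(fit$k, 15.4, tolerance = 1e-8)
  expect_equal(fit$x0, 3.5, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-6)
  # orthogonal variant agrees on noiseless data
  fo <- fit_universal_curve(pts, method = "orthogonal")
  expect_equal(fo$k, 15.4, tolerance = 1e-3)
})

test_that("universal fit is invariant to trial order and trial duplication", {
  lam <- c(0.3, 0.8, 1.5, 2.5, 4)
  withr::with_seed(5, {
    pts <- trial_points(af_from_lambda(lam),
                        24.5 * lam + 9.1 + rnorm(5, 0, 2))
  })
  f1 <- fit_universal_curve(pts)
  f2 <- fit_universal_curve(pts[rev(seq_len(nrow(pts))), ])
  expect_equal(f1$k, f2$k, tolerance = 1e-12)
  dup <- rbind(pts, pts)
  f3 <- fit_universal_curve(dup)
  expect_equal(f1$k, f3$k, tolerance = 1e-9)
})

test_that("degenerate universal-curve inputs are rejected or pinned", {
  lam <- rep(1, 6)
  expect_error(fit_universal_curve(trial_points(af_from_lambda(lam),
                                                10 + lam)),
               "identical")
  # slope-free data: tau constant -> k ~ 0, x0 ~ mean tau
  lam2 <- seq(0.2, 4, length.out = 8)
  fit <- fit_universal_curve(trial_points(af_from_lambda(lam2),
                                          rep(12, 8)))
  expect_equal(fit$k, 0, tolerance = 1e-9)
  expect_equal(fit$x0, 12, tolerance = 1e-9)
  expect_error(fit_universal_curve(trial_points(c(0.2, 0.5, 0.7),
                                                c(5, 10, 15))),
               "at least 5")
})

test_that("AF at 1 is capped and flagged rather than diverging", {
  pts <- trial_points(c(0.2, 0.5, 0.7, 0.9, 1.0), c(5, 10, 15, 25, 40))
  fit <- fit_universal_curve(pts)
  expect_true(any(grepl("capped", fit$flags)))
  expect_true(is.finite(fit$k))
})

test_that("off-rate is zero without detachment and Bell-like for single bonds", {
  # no detachment -> all rates 0
  cv <- build_detachment_curve(decay_trace(400, 0), "centrifuge_start",
                               t_origin = 120)
  prot <- assay_protocol(hold = 0)
  ftr <- force_trace(prot, cell_params(),
                     seq(120, min(prot$end_time, 360), by = 0.25))
  ftr$time_s <- ftr$time_s - 120
  orr <- off_rate_vs_force(cv[cv$time_s <= max(ftr$time_s), ], ftr)
  expect_true(all(orr$off_rate_per_s[is.finite(orr$off_rate_per_s)] == 0))
  expect_true(all(orr$off_rate_per_s[orr$n_available >= 5] == 0, na.rm = TRUE))
})

test_that("single-bond off-rate vs force recovers the Bell slope 1/f_beta", {
  k0 <- 1e-5; fb <- 10
  prot <- assay_protocol(hold = 0)
  tr <- simulate_trial(bond_model(lam = 1, k0 = k0, f_beta = fb), prot,
                       n_cells = 10000, bond_counts = rep(1L, 10000),
                       p_miss = 0, gravity_rupture = FALSE, seed = 9)
  cv <- build_detachment_curve(tr$count_trace, "centrifuge_start",
                               t_origin = 120, smoothing_window = 1)
  ftr <- force_trace(prot, cell_params(), seq(120, prot$end_time, by = 0.25))
  ftr$time_s <- ftr$time_s - 120
  orr <- off_rate_vs_force(cv, ftr, bin_width = 10)
  ok <- is.finite(orr$off_rate_per_s) & orr$off_rate_per_s > 0 &
    orr$n_detached >= 10 & orr$n_detached / orr$n_available < 0.3
  slope <- unname(coef(lm(log(off_rate_per_s) ~ force_pN, orr[ok, ]))[2])
  expect_equal(slope, 1 / fb, tolerance = 0.1)
})

test_that("misaligned time bases are rejected", {
  cv <- build_detachment_curve(decay_trace(400, 0.001), "centrifuge_start",
                               t_origin = 120)
  short <- data.frame(time_s = seq(0, 10, 0.5), force_pN = seq(0, 40, 2))
  expect_error(off_rate_vs_force(cv, short), "time span")
})
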