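# Detachment: adhesion frequency, curve construction, averaging.

test_that("adhesion frequency is the ratio of robust endpoint counts", {
  # constant counts -> AF = 1
  af <- adhesion_frequency(decay_trace(100, 0))
  expect_equal(af$adhesion_frequency, 1)
  # 200 cells at flip, 160 held: piecewise trace
  tms <- seq(0, 130, by = 0.25)
  counts <- ifelse(tms < 30, 200, 160)
  af <- adhesion_frequency(count_trace(tms, counts))
  expect_equal(af$adhesion_frequency, 0.8)
  expect_equal(af$n_initial, 200)
  expect_equal(af$n_after_gravity, 160)
})

test_that("adhesion frequency rejects empty starts and bad windows", {
  tms <- seq(0, 130, by = 0.25)
  expect_error(adhesion_frequency(count_trace(tms, rep(0, length(tms)))),
               "no cells")
  expect_error(adhesion_frequency(count_trace(tms, rep(5, length(tms))),
                                  t_flip = 100, t_centrifuge = 101),
               "overlap")
  expect_error(adhesion_frequency(count_trace(tms, rep(5, length(tms))),
                                  t_flip = 130, t_centrifuge = 120))
})

test_that("simulated adhesion frequency matches the Poisson closure at lambda = 1", {
  tr <- simulate_trial(bond_model(lam = 1), assay_protocol(hold = 0),
                       n_cells = 1000, seed = 21)
  af <- adhesion_frequency(tr$count_trace)
  expect_lt(abs(af$adhesion_frequency - (1 - exp(-1))),
            3 * sqrt(exp(-1) * (1 - exp(-1)) / 1000))
})

test_that("detachment curves normalize to 1 at the origin and track the survival", {
  # no detachment -> constant 1
  cv <- build_detachment_curve(decay_trace(150, 0), "centrifuge_start",
                               t_origin = 120)
  expect_equal(cv$fraction_bound, rep(1, nrow(cv)))
  expect_equal(attr(cv, "normalization_count"), 150)
  # exponential single-bond rupture at constant force: curve ~ exp(-k t)
  k0 <- 0.02
  prot <- ramp_protocol(120, rpm_for_force(10), end_time = 420)
  m <- bond_model(lam = 5, k0 = k0, f_beta = 1e6)  # force scale huge: rate ~ b*k0
  tr <- simulate_trial(m, prot, n_cells = 2000, bond_counts = rep(1L, 2000),
                       p_miss = 0, gravity_rupture = FALSE, seed = 4)
  cv <- build_detachment_curve(tr$count_trace, "centrifuge_start",
                               t_origin = 120, smoothing_window = 1)
  expected <- exp(-k0 * cv$time_s)
  expect_lt(max(abs(cv$fraction_bound - expected)), 0.05)
})

test_that("count jitter barely perturbs the median-filtered curve", {
  tms <- seq(0, 240, by = 0.25)
  base <- round(200 * exp(-pmax(tms - 120, 0) / 40))
  clean <- build_detachment_curve(count_trace(tms, base), "centrifuge_start",
                                  t_origin = 120)
  withr::with_seed(8, {
    jit <- pmax(base + sample(c(-1L, 0L, 1L), length(tms), replace = TRUE), 0)
  })
  noisy <- build_detachment_curve(count_trace(tms, jit), "centrifuge_start",
                                  t_origin = 120)
  expect_lt(max(abs(noisy$fraction_bound - clean$fraction_bound)), 0.05)
  # median-filtered curve is non-increasing up to the jitter tolerance
  expect_gt(min(diff(noisy$fraction_bound)), -0.05)
})

test_that("AF agrees with the flip-normalized curve evaluated before spin-up", {
  tr <- simulate_trial(bond_model(lam = 1.5), assay_protocol(hold = 0),
                       n_cells = 800, seed = 31)
  af <- adhesion_frequency(tr$count_trace)
  cv <- build_detachment_curve(tr$count_trace, "flip", t_origin = 2)
  at_spin <- approx(cv$time_s, cv$fraction_bound, xout = 118 - 2)$y
  expect_equal(af$adhesion_frequency, at_spin, tolerance = 0.05)
})

test_that("curve averaging produces pointwise means and SDs", {
  tms <- seq(0, 100, by = 1)
  c1 <- build_detachment_curve(count_trace(tms, rep(100, length(tms))),
                               "centrifuge_start", t_origin = 0)
  c0raw <- count_trace(tms, ifelse(tms <= 3, 100, 0))
  c0 <- build_detachment_curve(c0raw, "centrifuge_start", t_origin = 0,
                               smoothing_window = 1)
  avg <- average_curves(list(c1, c0), grid = seq(10, 90, by = 10))
  expect_equal(avg$mean_fraction, rep(0.5, 9))
  expect_equal(avg$sd_fraction, rep(sqrt(0.5), 9), tolerance = 1e-9)
  # identical curves -> zero SD
  same <- average_curves(list(c1, c1))
  expect_equal(same$sd_fraction, rep(0, nrow(same)))
  expect_error(average_curves(list(c1)), "at least two")
})

test_that("averaged simulator replicates track the generating survival", {
  prot <- assay_protocol(hold = 0)
  m <- bond_model(lam = 2, f_beta = 8)
  curves <- lapply(1:5, function(s) {
    tr <- simulate_trial(m, prot, n_cells = 500, seed = 40 + s)
    build_detachment_curve(tr$count_trace, "centrifuge_start", t_origin = 120)
  })
  grid <- seq(5, 115, by = 5)
  avg <- average_curves(curves, grid)
  # mean within 2 SD/sqrt(5) of itself is trivially true; instead check the
  # replicate band contains a reference replicate at >= 95% of points
  ref <- approx(curves[[1]]$time_s, curves[[1]]$fraction_bound, xout = grid)$y
  inside <- abs(ref - avg$mean_fraction) <=
    2 * pmax(avg$sd_fraction, 0.01) / sqrt(5) + 2 * sqrt(0.25 / 500) * 3
  expect_gte(mean(inside), 0.95)
})

test_that("monolayer QC flags coverage drops without dropping the trial", {
  tms <- seq(0, 120, by = 1)
  ok <- monolayer_qc(count_trace(tms, rep(50, 121),
                                 monolayer_counts = rep(300, 121)))
  expect_true(ok$ok)
  drop <- monolayer_qc(count_trace(tms, rep(50, 121),
                                   monolayer_counts = round(300 * exp(-tms / 100))))
  expect_false(drop$ok)
  none <- monolayer_qc(count_trace(tms, rep(50, 121)))
  expect_true(is.na(none$ok))
})

test_that("count traces round-trip through CSV", {
  tr <- decay_trace(80, 0.001, seq(0, 60, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_trace(tr, path)
  tr2 <- read_count_trace(path)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-9)
})
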