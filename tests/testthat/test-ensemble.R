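# Ensemble runs, settling/instability detectors, trial selection and
# onset-distribution fits.

cfg <- sim_config()

test_that("ensembles are deterministic given the seed and reduce to single runs", {
  e1 <- run_ensemble(5, cfg, controller_gains(), variant = "improved",
                     seed = 42, horizon = 0.8)
  e2 <- run_ensemble(5, cfg, controller_gains(), variant = "improved",
                     seed = 42, horizon = 0.8)
  expect_identical(e1$onsets, e2$onsets)
  expect_identical(e1$group_means, e2$group_means)
  expect_identical(e1$crash_fraction, e2$crash_fraction)
  # n = 1 is a single simulate_fall with the drawn onset
  e3 <- run_ensemble(1, cfg, controller_gains(), variant = "improved",
                     seed = 7, horizon = 0.8)
  tr <- simulate_fall(cfg, controller_gains(), onset = e3$onsets[1],
                      variant = "improved", horizon = 0.8)
  expect_equal(e3$trajectories[[1]]$states, tr$states)
})

test_that("crash fraction is a probability, monotone in the horizon", {
  g_weak <- controller_gains()
  eshort <- run_ensemble(8, cfg, g_weak, variant = "basic", seed = 5,
                         horizon = 0.6)
  elong <- run_ensemble(8, cfg, g_weak, variant = "basic", seed = 5,
                        horizon = 2)
  expect_gte(eshort$crash_fraction, 0)
  expect_lte(elong$crash_fraction, 1)
  expect_gte(elong$crash_fraction, eshort$crash_fraction)
})

test_that("onset groups are exhaustive, disjoint, and means are order-invariant", {
  e <- run_ensemble(12, cfg, controller_gains(), variant = "improved",
                    seed = 9, horizon = 0.6)
  expect_false(anyNA(e$groups))
  expect_equal(length(e$groups), 12)
  perm <- sample(12)
  gm_perm <- ensemble_group_means(e$trajectories[perm], e$groups[perm])
  expect_equal(gm_perm, e$group_means)
})

test_that("settling time: constant series, analytic exponential first-crossing", {
  t <- seq(0, 2, by = 1 / 1600)
  expect_equal(settling_time(t, rep(1.3, length(t))), 0)
  th0 <- 1; tau <- 0.1; band <- 0.1
  x <- th0 * exp(-t / tau)
  # |x - x_final| = band at t* = -tau log(band + exp(-T/tau))
  tstar <- -tau * log(band + exp(-max(t) / tau))
  expect_lt(abs(settling_time(t, x, band = band) - tstar), 2 / 1600)
})

test_that("instability detector fires exactly at a constructed crossing", {
  Ts <- cfg$Ts
  n <- 100; k <- 61
  th <- rep(0, n); th[k:n] <- 1.8        # exceeds pi/2 from sample k
  fake <- list(states = data.frame(t = (seq_len(n) - 1) * Ts,
                                   theta_p = th,
                                   omega_x = rep(-0.04, n)),
               onset = 0, diverged = FALSE,
               gains = controller_gains())
  expect_equal(instability_onset(fake), (k - 1) * Ts)
  # improved-model stable run: no instability
  tr <- simulate_fall(cfg, controller_gains(), onset = 0.1,
                      variant = "improved", horizon = 3)
  expect_true(is.na(instability_onset(tr)))
})

test_that("trial selection applies the onset and positive-climb rules", {
  tr_late <- simulate_fall(cfg, controller_gains(), onset = 0.16,
                           variant = "improved", horizon = 0.6)
  tr_ok <- simulate_fall(cfg, controller_gains(), onset = 0.1,
                         variant = "improved", horizon = 0.6)
  tr_fall <- simulate_fall(cfg, controller_gains(), onset = 0.1,
                           variant = "improved", horizon = 0.6,
                           force_scale = 0)
  sel <- select_trials(list(tr_late, tr_ok, tr_fall))
  expect_equal(sel$index, 2L)
  expect_equal(sel$n_kept, 1L)
  kept <- sel$selected[[1]]
  s <- kept$states
  # truncated at the first positive-vz instant
  expect_gt(tail(s$vz, 1), 0)
  expect_true(all(s$vz[-nrow(s)] <= 0))
  expect_lte(tail(s$t, 1), 0.1 + 0.300)
})

test_that("onset-distribution fits: degenerate, recovery, near-symmetric data", {
  f0 <- fit_onset_distribution(rep(103, 10))
  expect_true(f0$degenerate)
  expect_equal(f0$normal$mean, 103)
  expect_error(fit_onset_distribution(c(-1, 1, 2, 3, 4)), "non-positive")
  expect_error(fit_onset_distribution(c(1, 2)), "at least 5")

  set.seed(31)
  mu <- log(0.103) - 0.28^2 / 2
  x <- rlnorm(1e4, mu, 0.28)
  f <- fit_onset_distribution(x)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(f$lognormal$mean - 0.103), 2 * se + 1e-4)
  expect_equal(f$lognormal$meanlog, mu, tolerance = 0.01)
  # near-symmetric sample: both implied means within 1%
  expect_lt(abs(f$normal$mean - f$lognormal$mean) / f$normal$mean, 0.01)
})

test_that("closed-form MLEs agree with a generic optimizer", {
  skip_if_not_installed("MASS")
  set.seed(8)
  x <- rlnorm(500, meanlog = -2.3, sdlog = 0.3)
  f <- fit_onset_distribution(x)
  ref <- MASS::fitdistr(x, "lognormal")
  expect_equal(f$lognormal$meanlog, unname(ref$estimate["meanlog"]),
               tolerance = 1e-5)
  expect_equal(f$lognormal$sdlog, unname(ref$estimate["sdlog"]),
               tolerance = 1e-4)
  refn <- MASS::fitdistr(x, "normal")
  expect_equal(f$normal$mean, unname(refn$estimate["mean"]), tolerance = 1e-5)
})
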