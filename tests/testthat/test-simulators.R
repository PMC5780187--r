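# End-to-end free-fall simulations.

cfg <- sim_config()

test_that("state at wingbeat onset composes ballistics with passive pitch", {
  tr <- simulate_fall(cfg, controller_gains(), onset = 0.1,
                      variant = "basic", horizon = 0.4,
                      stop_at_floor = FALSE)
  s <- tr$states
  k <- which(abs(s$t - 0.1) < 1e-9)
  expect_equal(s$z[k] - cfg$box_height, -0.04905, tolerance = 1e-6)
  expect_equal(s$vz[k], -0.981, tolerance = 1e-9)
  expect_equal(s$theta_p[k], passive_pitch_response(0.1), tolerance = 1e-9)
  # the sample before onset still carries the passive pitch rate (at the
  # onset sample itself the halteres loop has taken over)
  expect_equal(s$theta_p_dot[k - 1],
               passive_pitch_response(0.1 - cfg$Ts, rate = TRUE),
               tolerance = 1e-9)
  # pre-onset: no force, passive pitch
  expect_true(all(s$F_mag[s$t < 0.1] == 0))
  expect_equal(s$theta_p[s$t < 0.1],
               passive_pitch_response(s$t[s$t < 0.1]), tolerance = 1e-9)
  expect_traj_invariants(tr)
})

test_that("free-fall phase is identical across variants and ballistic", {
  trb <- simulate_fall(cfg, controller_gains(), onset = 0.12,
                       variant = "basic", horizon = 0.3)
  tri <- simulate_fall(cfg, controller_gains(), onset = 0.12,
                       variant = "improved", horizon = 0.3)
  pre_b <- trb$states[trb$states$t < 0.12, ]
  pre_i <- tri$states[tri$states$t < 0.12, ]
  expect_equal(pre_b, pre_i)
  expect_equal(pre_b$z, cfg$box_height - 9.81 * pre_b$t^2 / 2,
               tolerance = 1e-12)
  expect_equal(pre_b$vz, -9.81 * pre_b$t, tolerance = 1e-12)
})

test_that("basic and improved simulators coincide when the extra loops are off", {
  g0 <- controller_gains(Kp_theta = 0, Kd_theta = 0, Kp_wz = 0, Ki_wz = 0)
  trb <- simulate_fall(cfg, g0, onset = 0.1, variant = "basic",
                       horizon = 0.35, stop_at_floor = FALSE)
  tri <- simulate_fall(cfg, g0, onset = 0.1, variant = "improved",
                       horizon = 0.35, stop_at_floor = FALSE)
  expect_equal(trb$states, tri$states, tolerance = 1e-12)
})

test_that("the basic model destabilizes a few hundred ms into the flight", {
  tr <- simulate_fall(cfg, controller_gains(), onset = 0.1,
                      variant = "basic", horizon = 3, stop_at_floor = FALSE)
  t_inst <- instability_onset(tr)
  expect_false(is.na(t_inst))
  expect_gt(t_inst, 0.2)
  expect_lt(t_inst, 0.55)
})

test_that("the improved model stabilizes: no crash, fast settling, altitude hold", {
  tr <- simulate_fall(cfg, controller_gains(), onset = 0.112,
                      variant = "improved", horizon = 3)
  expect_false(tr$crashed)
  expect_false(tr$diverged)
  post <- tr$states[tr$states$t >= tr$onset, ]
  expect_lte(settling_time(post$t, post$theta_p, band = 0.1), 0.150)
  # PI integral action cancels the vertical OF: altitude hold in steady state
  late <- tr$states[tr$states$t > 2.5, ]
  expect_lt(max(abs(late$vz)), 0.02)
  expect_lt(max(abs(late$omega_z)), 0.1)
  expect_lt(max(abs(late$theta_p)), 0.02)
  expect_traj_invariants(tr)
})

test_that("a weightless release from rest is an equilibrium", {
  cfg0 <- sim_config(g = 0)
  # with the forward-OF setpoint zeroed the state is an exact fixed point
  g0 <- controller_gains(omega_x_setpoint = 0)
  tr <- simulate_fall(cfg0, g0, onset = 0.1, variant = "improved",
                      horizon = 0.5)
  s <- tr$states
  expect_equal(max(abs(s$z - cfg0$box_height)), 0)
  expect_equal(max(abs(s$vx)), 0)
  expect_equal(max(abs(s$theta_p)), 0)
  expect_equal(max(abs(s$omega_x)), 0)
  expect_equal(max(abs(s$F_mag)), 0)
  # with the 0.04 setpoint the fly still never moves (no force, no flow),
  # only the commanded pitch seeks the unreachable forward flow
  tr2 <- simulate_fall(cfg0, controller_gains(), onset = 0.1,
                       variant = "improved", horizon = 0.5)
  expect_equal(max(abs(tr2$states$z - cfg0$box_height)), 0)
  expect_equal(max(abs(tr2$states$vx)), 0)
  expect_equal(max(abs(tr2$states$omega_x)), 0)
  expect_equal(max(abs(tr2$states$F_mag)), 0)
})

test_that("trajectory continuity: no super-physical state jumps", {
  tr <- simulate_fall(cfg, controller_gains(), onset = 0.1,
                      variant = "improved", horizon = 1)
  s <- tr$states
  fmax <- max(s$F_mag)
  expect_lte(max(abs(diff(s$vz))), cfg$Ts * (fmax + cfg$g) + 1e-12)
  expect_lte(max(abs(diff(s$vx))), cfg$Ts * fmax + 1e-12)
  expect_lte(max(abs(diff(s$z))), cfg$Ts * max(abs(s$vz)) + 1e-12)
})

test_that("crash detection: ballistic fall time, hover, censoring", {
  # no usable wing force: pure ballistic fall from 0.40 m
  tr <- simulate_fall(cfg, controller_gains(), onset = 0.1,
                      variant = "basic", horizon = 0.5, force_scale = 0)
  expect_true(tr$crashed)
  expect_equal(tr$crash_time, sqrt(2 * 0.40 / 9.81), tolerance = 2 * cfg$Ts)
  # clipped while still descending: censored, not crashed
  clipped <- list(states = data.frame(t = (0:10) / 1600, z = 0.3 - (0:10) / 100,
                                      vz = rep(-1, 11)))
  d <- detect_crash(clipped)
  expect_false(d$crashed)
  expect_true(is.na(d$crash_time))
  expect_true(d$censored)
  # hovering above the floor: neither crashed nor censored
  hover <- list(states = data.frame(t = (0:10) / 1600, z = rep(0.4, 11),
                                    vz = rep(0, 11)))
  d2 <- detect_crash(hover)
  expect_false(d2$crashed)
  expect_false(d2$censored)
})

test_that("horizons shorter than the onset are rejected", {
  expect_error(simulate_fall(cfg, controller_gains(), onset = 0.4,
                             horizon = 0.3), "horizon")
})
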