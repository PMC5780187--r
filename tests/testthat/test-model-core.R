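# Dynamic blocks and geometric relations of the flight model.

Ts <- 1 / 1600

test_that("wing-force step response hits its landmarks", {
  expect_equal(wing_force_response(0), 0, tolerance = 0.12)  # biproper leak only
  # final value theorem: 1.8955 * 9.81
  expect_equal(wing_force_response(5), 1.8955 * 9.81, tolerance = 1e-3)
  # independently computed (partial fractions): 20.276 m/s^2 at t = 0.4 s
  expect_equal(wing_force_response(0.4), 20.276, tolerance = 0.02)
  expect_true(all(wing_force_response(seq(0, 1, 0.01)) >= 0))
})

test_that("passive pitch is zero at release and strictly decreasing to 150 ms", {
  t <- seq(0, 0.15, by = Ts)
  th <- passive_pitch_response(t)
  expect_equal(th[1], 0, tolerance = 1e-9)
  expect_true(all(diff(th) < 0))
  # frozen from the continuous-time oracle (state-space integration):
  expect_equal(passive_pitch_response(0.15), -0.8734, tolerance = 0.01)
  # weightless variant: no driving torque, no rotation
  expect_equal(passive_pitch_response(t, g = 0), rep(0, length(t)))
})

test_that("passive pitch rate is consistent with the pitch series", {
  t <- seq(0, 0.15, by = Ts)
  th <- passive_pitch_response(t)
  thd <- passive_pitch_response(t, rate = TRUE)
  mid <- 2:(length(t) - 1)
  fd <- (th[mid + 1] - th[mid - 1]) / (2 * Ts)
  expect_lt(max(abs(thd[mid] - fd)), 0.1)
  expect_equal(thd[length(t)] / fd[length(mid)], 1, tolerance = 0.02)
})

test_that("lift/thrust decomposition is orthogonal to the body axis", {
  expect_equal(lift_thrust(0, 10), data.frame(F_mag = 10, L = 10, T = 0))
  r <- lift_thrust(-pi / 2, 10)
  expect_equal(r$L, 0, tolerance = 1e-12)
  expect_equal(r$T, 10)
  r2 <- lift_thrust(-pi / 4, 18.6)
  expect_equal(r2$L, 18.6 / sqrt(2), tolerance = 1e-9)
  expect_equal(r2$T, 18.6 / sqrt(2), tolerance = 1e-9)
  expect_error(lift_thrust(0, -1), "non-negative")
})

test_that("force magnitude is conserved across the pitch grid", {
  th <- seq(-pi / 2, pi / 2, length.out = 101)
  r <- lift_thrust(th, 12.3)
  expect_equal(r$L^2 + r$T^2, rep(12.3^2, 101), tolerance = 1e-9)
})

test_that("optic flow geometry: magnitude, components and conventions", {
  z0 <- optic_flow(0, 0, 0.3)
  expect_equal(unlist(z0), c(omega_mag = 0, theta_V_RI = 0,
                             theta_V_Rfly = 0, omega_x = 0, omega_z = 0))
  # pure vertical fall: |V|/d = 5; upward flow while falling
  f <- optic_flow(0, -1, 0, d_wall = 0.2)
  expect_equal(f$omega_mag, 5)
  expect_equal(f$omega_x, 0, tolerance = 1e-12)
  expect_equal(f$omega_z, 5)
  # pure horizontal motion: backward flow
  h <- optic_flow(1, 0, 0, d_wall = 0.2)
  expect_equal(h$omega_mag, 5)
  expect_equal(h$omega_x, -5)
  expect_equal(h$omega_z, 0, tolerance = 1e-12)
  expect_error(optic_flow(1, 0, 0, d_wall = 0), "d_wall")
})

test_that("optic-flow components conserve magnitude and rotate with pitch", {
  set.seed(4)
  vx <- rnorm(50); vz <- rnorm(50); th <- runif(50, -pi / 2, pi / 2)
  f <- optic_flow(vx, vz, th, 0.2)
  expect_equal(f$omega_x^2 + f$omega_z^2, f$omega_mag^2, tolerance = 1e-9)
  # fly frame = inertial frame rotated by -theta_p
  f0 <- optic_flow(vx, vz, 0, 0.2)
  expect_equal(f$omega_x, cos(th) * f0$omega_x + sin(th) * f0$omega_z,
               tolerance = 1e-9)
  expect_equal(f$omega_z, -sin(th) * f0$omega_x + cos(th) * f0$omega_z,
               tolerance = 1e-9)
})

test_that("visual PD: DC gain, derivative kick and input validation", {
  expect_equal(visual_pd(rep(0, 100), 5, 0.5), rep(0, 100))
  y <- visual_pd(rep(0.04, 4000), KpV = 5, KdV = 0.5, tau_d = 0.01)
  expect_equal(tail(y, 1), 0.2, tolerance = 1e-6)
  # first-sample jump of a unit step ~ KpV + KdV/tau_d, decaying to KpV
  y1 <- visual_pd(rep(1, 2000), KpV = 5, KdV = 0.5, tau_d = 0.01)
  expect_equal(y1[1], 5 + 0.5 / 0.01, tolerance = 0.05)
  expect_gt(y1[1], 10 * y1[2000])
  expect_equal(y1[2000], 5, tolerance = 1e-6)
  expect_error(visual_pd(0, 5, 0.5, tau_d = 0), "tau_d")
})

test_that("halteres loop equals the independently reduced closed-loop TF", {
  # independent block algebra: PI * lag under unity feedback
  pm <- function(p, q) convolve(p, rev(q), type = "open")
  ol_num <- pm(c(7, 0.3), 1)
  ol_den <- pm(c(1, 0), c(0.002, 1))
  cl_num <- ol_num
  cl_den <- c(0, ol_num) + ol_den          # den + num (pad to same order)
  blk <- discretize_lti(cl_num, cl_den, Ts = Ts)
  u <- c(rep(0, 10), rep(1, 300))
  expect_equal(halteres_loop_step(u), lti_filter(blk, u), tolerance = 1e-9)
})

test_that("halteres loop tracks constant setpoints with zero steady-state error", {
  expect_equal(halteres_loop_step(rep(0, 100)), rep(0, 100))
  # integral action: DC gain exactly 1, but the near-cancelled slow pole
  # (~27 s time constant) means convergence takes minutes of flight time
  expect_equal(dc_gain(tf_halteres_loop()), 1)
  n <- round(150 / Ts)
  y <- halteres_loop_step(rep(1, n))
  expect_lt(abs(tail(y, 1) - 1), 1e-3)
  expect_equal(halteres_loop_step(rep(1, 2000))[2000], 0.875, tolerance = 0.01)
})

test_that("halteres loop matches a continuous-time ODE oracle", {
  hal <- tf_halteres_loop()
  t <- seq(0, 0.5, by = Ts)
  y <- halteres_loop_step(rep(1, length(t)))
  oracle <- step_response_pf(hal$num, hal$den, t + Ts / 2, 1)
  # first samples hide the sub-sample actuator transient (0.25 ms pole)
  expect_lt(max(abs(y - oracle)[-(1:3)]), 1e-3)
})

test_that("kinematic integration reproduces ballistic closed forms", {
  st <- list(t = 0, x = 0, z = 0.40, vx = 0, vz = 0, theta_p = 0,
             theta_p_dot = 0)
  for (k in 1:160) st <- integrate_kinematics(st, L = 0, T = 0)
  expect_equal(st$vz, -9.81 * 0.1, tolerance = 1e-12)
  expect_lt(abs(st$z - 0.40 + 0.049), 5e-4)
  # hover: L = g keeps vz constant
  st2 <- list(t = 0, x = 0, z = 1, vx = 0, vz = -0.3, theta_p = 0,
              theta_p_dot = 0)
  st2 <- integrate_kinematics(st2, L = 9.81, T = 0)
  expect_equal(st2$vz, -0.3)
  # L = 2g for 0.1 s from vz = -0.981 brings vz to zero
  st3 <- list(t = 0, x = 0, z = 1, vx = 0, vz = -0.981, theta_p = 0,
              theta_p_dot = 0)
  for (k in 1:160) st3 <- integrate_kinematics(st3, L = 2 * 9.81, T = 0)
  expect_equal(st3$vz, 0, tolerance = 1e-12)
})

test_that("configuration and gain validation", {
  expect_error(sim_config(d_wall = -1))
  expect_error(sim_config(onset_window = c(0.2, 0.1)))
  expect_error(sim_config(onset_window = c(0.1, 0.6), horizon = 0.5),
               "onset_window")
  expect_error(controller_gains(tau_d = 0), "tau_d")
  expect_error(controller_gains(KpV = Inf), "finite")
  g <- controller_gains()
  expect_equal(g$KpH, 7)
  expect_equal(g$KiH, 0.3)
  expect_equal(g$omega_x_setpoint, 0.04)
  expect_equal(sim_config()$Ts, 1 / 1600)
})
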