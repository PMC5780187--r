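# Dynamic blocks and geometric relations of the free-fall flight model.
#
# Conventions (used throughout the package):
#   * z up, floor at z = 0, release at z = box_height (0.40 m).
#   * pitch theta_p: 0 = horizontal, negative = head-down; valid body
#     orientations live in [-pi/2, pi/2].
#   * forces are mass-normalized (accelerations, m/s^2); no mass parameter.
#   * optic flow (OF): translational OF magnitude is |V|/d_wall (rad/s).
#     Reported OF components (omega_x, omega_z) use the flow-opposite
#     convention: the OF vector is the negated velocity direction in the fly
#     frame, so omega_z > 0 while falling and steady forward flight gives
#     omega_x < 0.  The controllers consume the velocity-projection
#     convention (positive when moving forward/up), i.e. the negation.

#' Simulation configuration
#'
#' Physical constants and sampling settings of the free-fall experiment:
#' a 0.40 m drop filmed at 1600 Hz in a corridor whose textured walls are
#' 0.20 m away on either side.
#'
#' @param d_wall distance to the textured wall (m).
#' @param box_height release height above the floor (m).
#' @param g gravity magnitude (m/s^2).
#' @param Ts sample period (s); 1/1600 s matches the camera frame rate.
#' @param onset_window interval (s) from which wingbeat-onset times are
#'   drawn.
#' @param horizon default simulation length (s).
#' @param seed optional RNG seed recorded with the configuration.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(d_wall = 0.20, box_height = 0.40, g = 9.81,
                       Ts = 1 / 1600, onset_window = c(0.075, 0.150),
                       horizon = 0.5, seed = NULL) {
  stopifnot(is.numeric(d_wall), d_wall > 0,
            is.numeric(box_height), box_height > 0,
            is.numeric(g), g >= 0,
            is.numeric(Ts), Ts > 0,
            is.numeric(horizon), horizon > 0,
            length(onset_window) == 2, all(onset_window > 0),
            onset_window[1] <= onset_window[2])
  if (onset_window[2] >= horizon)
    stop("onset_window must lie within (0, horizon)")
  structure(list(d_wall = d_wall, box_height = box_height, g = g, Ts = Ts,
                 onset_window = onset_window, horizon = horizon, seed = seed),
            class = "sim_config")
}

#' Controller gains
#'
#' Gains of the nested control loops.  The halteres pitch-rate loop is a PI
#' controller with `KpH = 7`, `KiH = 0.3` (fixed, from prior work on
#' fruitflies); the visual loop regulating the forward optic flow toward the
#' `omega_x_setpoint` is a PD controller with a filtered derivative whose
#' gains `KpV`, `KdV` are the free parameters identified by
#' [mle_grid()].  The remaining gains belong only to the improved model
#' variant: a PI force loop on the vertical optic flow (`Kp_wz`, `Ki_wz`)
#' and a PD pitch-rate loop on the absolute pitch (`Kp_theta`, `Kd_theta`).
#'
#' @param KpH,KiH halteres PI gains (dimensionless).
#' @param KpV,KdV visual PD gains on the forward-OF error.
#' @param tau_d derivative filter time constant (s) shared by the PD blocks.
#' @param omega_x_setpoint forward-OF reference, in the internal OF units
#'   (|V|/d_wall, rad/s).
#' @param Kp_theta,Kd_theta absolute-pitch PD gains (improved model).
#' @param Kp_wz,Ki_wz vertical-OF PI force gains (improved model).
#' @return a validated list of class `controller_gains`.
#' @export
controller_gains <- function(KpH = 7, KiH = 0.3,
                             KpV = 5, KdV = 0.5,
                             tau_d = 0.01, omega_x_setpoint = 0.04,
                             Kp_theta = 20, Kd_theta = 1,
                             Kp_wz = 8, Ki_wz = 40) {
  vals <- c(KpH = KpH, KiH = KiH, KpV = KpV, KdV = KdV, tau_d = tau_d,
            omega_x_setpoint = omega_x_setpoint, Kp_theta = Kp_theta,
            Kd_theta = Kd_theta, Kp_wz = Kp_wz, Ki_wz = Ki_wz)
  if (!all(is.finite(vals))) stop("all gains must be finite")
  if (tau_d <= 0) stop("tau_d must be > 0")
  structure(as.list(vals), class = "controller_gains")
}

# ---- canonical blocks -----------------------------------------------------

#' Flapping-wing force transfer function
#'
#' Second-order low-pass with a zero,
#' `C_WB(s) = (0.24 s + 1.8955) / (0.01 s^2 + 0.1 s + 1)`, whose response to
#' a gravity-sized step models the build-up of the mass-normalized wing
#' force after wingbeat onset.
#'
#' @return an `lti_tf`.
#' @export
tf_wing_force <- function() lti_tf(c(0.24, 1.8955), c(0.01, 0.1, 1))

#' Passive pitch-down transfer function
#'
#' Fifth-order block
#' `T_passive(s) = (0.001 s^2 + 30 s) / (s^2 (0.0011 s^3 + 0.0005 s^2 + 0.01 s + 1))`
#' fitted to averaged pre-wingbeat pitch recordings; its response to a step
#' of amplitude -pi/2 gives the passive nose-down pitch during the fall.
#' Note the cubic factor has a pair of unstable roots, so the block is only
#' meaningful on the short pre-wingbeat window (onsets are at most 150 ms).
#'
#' @return an `lti_tf`.
#' @export
tf_passive_pitch <- function()
  lti_tf(c(0.001, 30, 0), .polymul(c(1, 0, 0), c(0.0011, 0.0005, 0.01, 1)))

#' Visual PD controller with filtered derivative
#'
#' `PD_V(s) = KpV + KdV s / (tau_d s + 1)`.
#'
#' @inheritParams controller_gains
#' @return an `lti_tf`.
#' @export
tf_visual_pd <- function(KpV, KdV, tau_d = 0.01) {
  if (tau_d <= 0) stop("tau_d must be > 0")
  lti_tf(c(KpV * tau_d + KdV, KpV), c(tau_d, 1))
}

#' Halteres closed-loop pitch-rate dynamics
#'
#' The inner loop: PI controller `KpH + KiH/s` cascaded with a first-order
#' wing-pitch actuator lag (time constant `actuator_lag`), closed with unity
#' feedback on the measured pitch rate.  Reduced algebraically to
#' `(KpH s + KiH) / (lag s^2 + (1 + KpH) s + KiH)`; the reduction is exact
#' because every element of the loop is linear.
#'
#' @inheritParams controller_gains
#' @param actuator_lag wing-pitch actuator time constant (s).
#' @return an `lti_tf`.
#' @export
tf_halteres_loop <- function(KpH = 7, KiH = 0.3, actuator_lag = 0.002) {
  lti_tf(c(KpH, KiH), c(actuator_lag, 1 + KpH, KiH))
}

# ---- operations -----------------------------------------------------------

#' Wing-force step response
#'
#' Mass-normalized force magnitude produced by the flapping wings at times
#' `t` after wingbeat onset: the response of [tf_wing_force()] to a step of
#' amplitude `g`, clamped at zero from below.  It peaks near 25.8 m/s^2
#' around 0.22 s and settles to 1.8955 g (about 18.6 m/s^2).
#'
#' @param t times since onset (s), non-negative.
#' @param g step amplitude (gravity magnitude, m/s^2).
#' @param Ts simulation step (s).
#' @return force magnitudes (m/s^2) at the sample grid points nearest `t`.
#' @export
wing_force_response <- function(t, g = 9.81, Ts = 1 / 1600) {
  stopifnot(all(t >= 0))
  blk <- discretize_lti(tf_wing_force(), Ts = Ts)
  n <- max(as.integer(round(max(t) / Ts)) + 1L, 1L)
  y <- lti_filter(blk, rep(g, n))
  pmax(y[pmin(as.integer(round(t / Ts)) + 1L, n)], 0)
}

#' Passive pitch response during the fall
#'
#' Pitch contribution of the passive nose-down torque before wingbeat
#' initiation: response of [tf_passive_pitch()] to a step of amplitude
#' `-pi/2 * g / 9.81` (the torque comes from the fall, so it vanishes in a
#' weightless variant).  Only the pre-onset window (t at most ~0.15 s) is
#' physically meaningful.
#'
#' @param t times since release (s), non-negative.
#' @param g gravity magnitude (m/s^2); scales the driving step.
#' @param Ts simulation step (s).
#' @param rate if `TRUE` return the pitch rate (response of
#'   `s * T_passive(s)`) instead of the pitch.
#' @return pitch (rad) or pitch rate (rad/s) at the grid points nearest `t`.
#' @export
passive_pitch_response <- function(t, g = 9.81, Ts = 1 / 1600, rate = FALSE) {
  stopifnot(all(t >= 0))
  tf <- tf_passive_pitch()
  if (rate) tf <- lti_tf(c(tf$num, 0), tf$den)  # multiply numerator by s
  blk <- discretize_lti(tf, Ts = Ts)
  n <- max(as.integer(round(max(t) / Ts)) + 1L, 1L)
  amp <- -pi / 2 * g / 9.81
  y <- lti_filter(blk, rep(amp, n))
  y[pmin(as.integer(round(t / Ts)) + 1L, n)]
}

#' Decompose the wing force into lift and thrust
#'
#' The wing force is orthogonal to the body axis, so
#' `L = sin(theta_p + pi/2) |F| = cos(theta_p) |F|` (vertical, inertial
#' frame) and `T = cos(theta_p + pi/2) |F| = -sin(theta_p) |F|`
#' (horizontal): a head-down pitch converts force into forward thrust.
#'
#' @param theta_p body pitch (rad).
#' @param F_mag force magnitude (m/s^2), non-negative.
#' @return data.frame with columns `F_mag`, `L`, `T`.
#' @export
lift_thrust <- function(theta_p, F_mag) {
  if (any(F_mag < 0)) stop("F_mag must be non-negative")
  data.frame(F_mag = F_mag,
             L = cos(theta_p) * F_mag,
             T = -sin(theta_p) * F_mag)
}

#' Translational optic flow seen by the fly
#'
#' Magnitude `|V| / d_wall` with the direction opposite to the velocity,
#' expressed in the fly frame (rotation by `-theta_p`).  `omega_x` and
#' `omega_z` are the flow-opposite components; the velocity-projection
#' components the controllers use are their negation.
#'
#' @param vx,vz inertial-frame velocity components (m/s).
#' @param theta_p body pitch (rad).
#' @param d_wall distance to the wall (m), positive.
#' @return data.frame with columns `omega_mag`, `theta_V_RI`,
#'   `theta_V_Rfly`, `omega_x`, `omega_z`.
#' @export
optic_flow <- function(vx, vz, theta_p, d_wall = 0.20) {
  if (any(d_wall <= 0)) stop("d_wall must be > 0")
  speed <- sqrt(vx^2 + vz^2)
  th_v <- ifelse(speed > 0, atan2(vz, vx), 0)
  th_v_fly <- ifelse(speed > 0, th_v - theta_p, 0)
  mag <- speed / d_wall
  data.frame(omega_mag = mag,
             theta_V_RI = th_v,
             theta_V_Rfly = th_v_fly,
             omega_x = -mag * cos(th_v_fly),
             omega_z = -mag * sin(th_v_fly))
}

#' Visual PD controller output
#'
#' Runs the filtered-derivative PD block [tf_visual_pd()] over a uniformly
#' sampled forward-OF error sequence, producing the commanded pitch rate.
#' For a constant error `e` the output settles at `KpV * e`; the first
#' sample after a step jumps by about `(KpV + KdV / tau_d)` times the step.
#'
#' @param omega_x_error forward-OF error sequence (rad/s), sampled at `Ts`.
#' @inheritParams controller_gains
#' @param Ts sample period (s).
#' @return commanded pitch-rate sequence (rad/s).
#' @export
visual_pd <- function(omega_x_error, KpV, KdV, tau_d = 0.01, Ts = 1 / 1600) {
  blk <- discretize_lti(tf_visual_pd(KpV, KdV, tau_d), Ts = Ts)
  lti_filter(blk, omega_x_error)
}

#' Closed-loop pitch-rate tracking by the halteres
#'
#' Response of the halteres inner loop [tf_halteres_loop()] to a pitch-rate
#' setpoint sequence.  Integral action gives zero steady-state error for any
#' constant setpoint.
#'
#' @param theta_p_dot_star pitch-rate setpoint sequence (rad/s) at `Ts`.
#' @inheritParams tf_halteres_loop
#' @param Ts sample period (s).
#' @return achieved pitch-rate sequence (rad/s).
#' @export
halteres_loop_step <- function(theta_p_dot_star, KpH = 7, KiH = 0.3,
                               actuator_lag = 0.002, Ts = 1 / 1600) {
  blk <- discretize_lti(tf_halteres_loop(KpH, KiH, actuator_lag), Ts = Ts)
  lti_filter(blk, theta_p_dot_star)
}

#' One kinematic integration step
#'
#' Semi-implicit Euler update of the planar body state under mass-normalized
#' lift `L` and thrust `T`: velocities first
#' (`vz <- vz + Ts (L - g)`, `vx <- vx + Ts T`), then positions with the
#' updated velocities, then pitch with the supplied pitch rate.
#'
#' @param state list or one-row data.frame with `t`, `x`, `z`, `vx`, `vz`,
#'   `theta_p`, `theta_p_dot`.
#' @param L,T mass-normalized lift and thrust (m/s^2).
#' @param g gravity magnitude (m/s^2).
#' @param Ts step (s).
#' @return the updated state (list).
#' @export
integrate_kinematics <- function(state, L, T, g = 9.81, Ts = 1 / 1600) {
  vz <- state$vz + Ts * (L - g)
  vx <- state$vx + Ts * T
  list(t = state$t + Ts,
       x = state$x + Ts * vx,
       z = state$z + Ts * vz,
       vx = vx, vz = vz,
       theta_p = state$theta_p + Ts * state$theta_p_dot,
       theta_p_dot = state$theta_p_dot)
}
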