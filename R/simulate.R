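# End-to-end free-fall simulations: passive ballistic phase composed with
# the closed-loop flight phase (basic or improved variant).

# Precompute everything that does not depend on (KpV, KdV): the passive
# phase, the initial state at onset, the wing-force baseline and the
# discretized inner-loop blocks.  mle_grid() reuses one prep across the
# whole candidate grid.
.prep_sim <- function(config, gains, onset, variant, horizon,
                      stop_at_floor = TRUE, force_scale = 1) {
  stopifnot(inherits(config, "sim_config"), inherits(gains, "controller_gains"))
  variant <- match.arg(variant, c("basic", "improved"))
  if (horizon <= onset) stop("horizon must exceed the wingbeat onset time")
  Ts <- config$Ts
  g <- config$g
  i_on <- as.integer(round(onset / Ts))
  onset_eff <- i_on * Ts
  n_total <- as.integer(floor(horizon / Ts)) + 1L
  n_post <- n_total - i_on
  if (n_post < 1L) stop("horizon must exceed the wingbeat onset time")

  # passive phase: frictionless ballistic fall + passive pitch-down
  t_pre <- if (i_on > 0) (seq_len(i_on) - 1L) * Ts else numeric(0)
  amp <- -pi / 2 * g / 9.81
  if (i_on > 0) {
    blk_th <- discretize_lti(tf_passive_pitch(), Ts = Ts)
    tfr <- tf_passive_pitch()
    blk_thd <- discretize_lti(lti_tf(c(tfr$num, 0), tfr$den), Ts = Ts)
    u <- rep(amp, i_on + 1L)
    th_pre_full <- lti_filter(blk_th, u)
    thd_pre_full <- lti_filter(blk_thd, u)
  } else {
    th_pre_full <- 0
    thd_pre_full <- 0
  }
  pre <- list(t = t_pre,
              x = rep(0, i_on), z = config$box_height - g * t_pre^2 / 2,
              vx = rep(0, i_on), vz = -g * t_pre,
              theta_p = th_pre_full[seq_len(i_on)],
              theta_p_dot = thd_pre_full[seq_len(i_on)])

  state0 <- list(x = 0,
                 z = config$box_height - g * onset_eff^2 / 2,
                 vx = 0, vz = -g * onset_eff,
                 theta_p = th_pre_full[i_on + 1L],
                 theta_p_dot = thd_pre_full[i_on + 1L])

  f_blk <- discretize_lti(tf_wing_force(), Ts = Ts)
  f_base <- force_scale * pmax(lti_filter(f_blk, rep(g, n_post)), 0)

  hal <- discretize_lti(tf_halteres_loop(gains$KpH, gains$KiH), Ts = Ts)
  pdth <- discretize_lti(tf_visual_pd(gains$Kp_theta, gains$Kd_theta,
                                      gains$tau_d), Ts = Ts)
  piwz <- discretize_lti(lti_tf(c(gains$Kp_wz, gains$Ki_wz), c(1, 0)),
                         Ts = Ts)

  list(config = config, gains = gains, variant = variant,
       onset = onset_eff, i_on = i_on, horizon = horizon,
       n_post = n_post, pre = pre, state0 = state0, f_base = f_base,
       hal = hal, pdth = pdth, piwz = piwz, stop_at_floor = stop_at_floor)
}

# Run the post-onset loop for one candidate visual gain pair.
.run_prepped <- function(prep, KpV = prep$gains$KpV, KdV = prep$gains$KdV) {
  g <- prep$gains
  pd <- discretize_lti(tf_visual_pd(KpV, KdV, g$tau_d), Ts = prep$config$Ts)
  sim_fall_post_cpp(prep$config$Ts, prep$config$g, prep$config$d_wall,
                    g$omega_x_setpoint,
                    prep$state0$x, prep$state0$z, prep$state0$vx,
                    prep$state0$vz, prep$state0$theta_p,
                    prep$state0$theta_p_dot,
                    prep$f_base, pd$b, pd$a, prep$hal$b, prep$hal$a,
                    prep$variant == "improved",
                    prep$pdth$b, prep$pdth$a, prep$piwz$b, prep$piwz$a,
                    pi, 50, prep$stop_at_floor,
                    exp(-prep$config$Ts / 0.002))
}

.assemble_trajectory <- function(prep, post, KpV, KdV) {
  Ts <- prep$config$Ts
  i_on <- prep$i_on
  nu <- post$n_used
  idx <- seq_len(nu)
  pre <- prep$pre
  pre_of <- if (i_on > 0) {
    optic_flow(pre$vx, pre$vz, pre$theta_p, prep$config$d_wall)
  } else {
    NULL
  }
  states <- data.frame(
    t = c(pre$t, prep$onset + (idx - 1L) * Ts),
    x = c(pre$x, post$x[idx]),
    z = c(pre$z, post$z[idx]),
    vx = c(pre$vx, post$vx[idx]),
    vz = c(pre$vz, post$vz[idx]),
    theta_p = c(pre$theta_p, post$theta_p[idx]),
    theta_p_dot = c(pre$theta_p_dot, post$theta_p_dot[idx]),
    F_mag = c(rep(0, i_on), post$F_mag[idx]),
    L = c(rep(0, i_on), post$L[idx]),
    T = c(rep(0, i_on), post$T[idx]),
    omega_x = c(if (i_on > 0) pre_of$omega_x, post$omega_x[idx]),
    omega_z = c(if (i_on > 0) pre_of$omega_z, post$omega_z[idx]))
  gains <- prep$gains
  gains$KpV <- KpV
  gains$KdV <- KdV
  traj <- structure(list(states = states,
                         onset = prep$onset,
                         variant = prep$variant,
                         crashed = isTRUE(post$crashed),
                         crash_time = NA_real_,
                         diverged = isTRUE(post$diverged),
                         config = prep$config,
                         gains = gains),
                    class = "fall_trajectory")
  cr <- detect_crash(traj)
  traj$crashed <- cr$crashed
  traj$crash_time <- cr$crash_time
  traj
}

#' Simulate one free fall with closed-loop recovery
#'
#' Phase 1 (t < onset): frictionless ballistic fall with the passive
#' pitch-down block driving the pitch.  Phase 2 (t >= onset): the wing
#' force follows its step response, the visual PD controller turns the
#' forward-OF error into a pitch-rate command tracked by the halteres loop,
#' and the kinematics close the loop through the optic-flow geometry.  The
#' `improved` variant adds a PI force loop cancelling the vertical optic
#' flow (force clamped at zero from below) and a PD pitch-rate loop on the
#' absolute pitch.
#'
#' The simulation halts and is flagged `diverged` when |pitch| exceeds pi
#' or speed exceeds 50 m/s, and (by default) stops at the first floor
#' contact.
#'
#' @param config a [sim_config()].
#' @param gains a [controller_gains()].
#' @param onset wingbeat onset time (s); rounded to the sample grid.
#' @param variant `"basic"` or `"improved"`.
#' @param horizon simulation length (s), must exceed `onset`.
#' @param stop_at_floor stop at the first sample with z <= 0.
#' @param force_scale multiplier on the wing-force baseline; 0 emulates
#'   wingbeats that produce no usable force (non-recovering trials).
#' @return an object of class `fall_trajectory`: a list with `states`
#'   (per-sample data.frame: `t, x, z, vx, vz, theta_p, theta_p_dot, F_mag,
#'   L, T, omega_x, omega_z`), `onset`, `variant`, `crashed`, `crash_time`,
#'   `diverged`, `config`, `gains`.
#' @export
simulate_fall <- function(config = sim_config(), gains = controller_gains(),
                          onset = 0.1, variant = c("basic", "improved"),
                          horizon = config$horizon, stop_at_floor = TRUE,
                          force_scale = 1) {
  variant <- match.arg(variant)
  prep <- .prep_sim(config, gains, onset, variant, horizon, stop_at_floor,
                    force_scale)
  post <- .run_prepped(prep)
  .assemble_trajectory(prep, post, gains$KpV, gains$KdV)
}

#' @export
print.fall_trajectory <- function(x, ...) {
  cat(sprintf("<fall_trajectory: %s model, onset %.1f ms, %d samples>\n",
              x$variant, 1000 * x$onset, nrow(x$states)))
  cat(sprintf("  crashed: %s%s  diverged: %s\n",
              x$crashed,
              if (x$crashed) sprintf(" (t = %.3f s)", x$crash_time) else "",
              x$diverged))
  invisible(x)
}

#' Detect the first floor contact of a trajectory
#'
#' @param traj a `fall_trajectory` (or any list with a `states` data.frame
#'   holding `t`, `z` and `vz`).
#' @param floor_z floor height (m).
#' @return list with `crashed` (flag), `crash_time` (s, `NA` if never) and
#'   `censored` (`TRUE` when the trajectory ends above the floor while
#'   still descending, i.e. the horizon clipped a possible crash).
#' @export
detect_crash <- function(traj, floor_z = 0) {
  s <- traj$states
  if (nrow(s) == 0) stop("empty trajectory")
  hit <- which(s$z <= floor_z)
  if (length(hit) > 0) {
    list(crashed = TRUE, crash_time = s$t[hit[1]], censored = FALSE)
  } else {
    desc <- s$vz[nrow(s)] < 0
    list(crashed = FALSE, crash_time = NA_real_, censored = desc)
  }
}
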