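# Identification of the visual PD gains (KpV, KdV) by maximum likelihood
# on a grid, one likelihood map per observed fall, averaged across falls;
# plus a structural re-fit of the passive pitch-down transfer function.

.as_observed_pitch <- function(observed) {
  if (inherits(observed, "fall_trajectory")) {
    s <- observed$states
    post <- s$t >= observed$onset
    return(list(onset = observed$onset, t = s$t[post],
                theta_p = s$theta_p[post]))
  }
  stopifnot(is.list(observed), !is.null(observed$onset),
            !is.null(observed$t), !is.null(observed$theta_p))
  observed
}

.loglik_prepped <- function(prep, obs_th, KpV, KdV, noise_sd) {
  post <- .run_prepped(prep, KpV, KdV)
  n <- length(obs_th)
  if (post$n_used < n) return(-Inf)      # diverged/ended inside the window
  resid <- obs_th - post$theta_p[seq_len(n)]
  if (!all(is.finite(resid))) return(-Inf)
  sum(dnorm(resid, mean = 0, sd = noise_sd, log = TRUE))
}

#' Gaussian log-likelihood of an observed pitch series under candidate gains
#'
#' Simulates a fall with the observed onset and the candidate visual gains,
#' and scores the observed pitch residuals over the post-onset comparison
#' window under iid Gaussian measurement noise (`noise_sd`, default the
#' 0.08 rad pitch-tracking error of the stereo reconstruction).  A
#' simulation that diverges before the end of the window scores `-Inf`.
#'
#' @param observed a `fall_trajectory`, or a list with `onset` (s), `t`
#'   (absolute times, s) and `theta_p` (rad) for the post-onset samples.
#' @param KpV,KdV candidate visual PD gains.
#' @param config a [sim_config()].
#' @param gains base [controller_gains()] supplying every other gain.
#' @param variant model variant to simulate (the identification in the
#'   study fits the basic model).
#' @param noise_sd pitch measurement noise (rad).
#' @param window comparison window after onset (s).
#' @return scalar log-likelihood.
#' @export
trajectory_loglik <- function(observed, KpV, KdV, config = sim_config(),
                              gains = controller_gains(),
                              variant = "basic", noise_sd = 0.08,
                              window = 0.2) {
  obs <- .as_observed_pitch(observed)
  Ts <- config$Ts
  n_win <- as.integer(round(window / Ts))
  if (length(obs$theta_p) < n_win)
    stop("observed series must cover at least ", window, " s after onset")
  prep <- .prep_sim(config, gains, obs$onset, variant,
                    horizon = obs$onset + window + 2 * Ts,
                    stop_at_floor = FALSE)
  .loglik_prepped(prep, obs$theta_p[seq_len(n_win)], KpV, KdV, noise_sd)
}

.argmax_low_complexity <- function(m, Kp_grid, Kd_grid) {
  # ties broken toward smaller KdV, then smaller KpV
  best <- max(m)
  cand <- which(m == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  c(KpV = Kp_grid[cand[1, 1]], KdV = Kd_grid[cand[1, 2]])
}

#' Maximum-likelihood grid estimation of the visual PD gains
#'
#' For each observed fall, evaluates [trajectory_loglik()] over a
#' `Kp_grid` x `Kd_grid` lattice (defaults: 41 x 41 over KpV in [0, 20],
#' KdV in [0, 2]), producing one likelihood map per fall; the maps are
#' averaged element-wise and the selected gains are the argmax of the
#' averaged map, with ties broken toward the lowest-complexity controller
#' (smaller KdV, then smaller KpV).
#'
#' @param observed_set list of observed falls (see [trajectory_loglik()]).
#' @param Kp_grid,Kd_grid candidate gain grids.
#' @inheritParams trajectory_loglik
#' @return an object of class `likelihood_maps`: list with `maps` (one
#'   matrix per fall, rows = KpV, cols = KdV), `average` (mean map),
#'   `selected` (named vector `KpV`, `KdV`), `per_fall_argmax` (data.frame
#'   of per-map argmaxes), `Kp_grid`, `Kd_grid`.
#' @export
mle_grid <- function(observed_set,
                     Kp_grid = seq(0, 20, length.out = 41),
                     Kd_grid = seq(0, 2, length.out = 41),
                     config = sim_config(), gains = controller_gains(),
                     variant = "basic", noise_sd = 0.08, window = 0.2) {
  stopifnot(length(observed_set) >= 1,
            length(Kp_grid) >= 1, length(Kd_grid) >= 1)
  if (any(Kp_grid < 0) || any(Kp_grid > 20) ||
      any(Kd_grid < 0) || any(Kd_grid > 2))
    stop("estimation grids are contracted to KpV in [0, 20], KdV in [0, 2]")
  Ts <- config$Ts
  n_win <- as.integer(round(window / Ts))
  maps <- lapply(observed_set, function(observed) {
    obs <- .as_observed_pitch(observed)
    if (length(obs$theta_p) < n_win)
      stop("an observed series is shorter than the comparison window")
    prep <- .prep_sim(config, gains, obs$onset, variant,
                      horizon = obs$onset + window + 2 * Ts,
                      stop_at_floor = FALSE)
    obs_th <- obs$theta_p[seq_len(n_win)]
    m <- matrix(NA_real_, length(Kp_grid), length(Kd_grid))
    for (j in seq_along(Kd_grid))
      for (i in seq_along(Kp_grid))
        m[i, j] <- .loglik_prepped(prep, obs_th, Kp_grid[i], Kd_grid[j],
                                   noise_sd)
    m
  })
  avg <- Reduce(`+`, maps) / length(maps)
  per_fall <- do.call(rbind, lapply(maps, function(m)
    as.data.frame(as.list(.argmax_low_complexity(m, Kp_grid, Kd_grid)))))
  structure(list(maps = maps, average = avg,
                 selected = .argmax_low_complexity(avg, Kp_grid, Kd_grid),
                 per_fall_argmax = per_fall,
                 Kp_grid = Kp_grid, Kd_grid = Kd_grid),
            class = "likelihood_maps")
}

#' @export
print.likelihood_maps <- function(x, ...) {
  cat(sprintf("<likelihood_maps: %d falls, %d x %d grid>\n",
              length(x$maps), length(x$Kp_grid), length(x$Kd_grid)))
  cat(sprintf("  selected gains: KpV = %.3g, KdV = %.3g\n",
              x$selected["KpV"], x$selected["KdV"]))
  invisible(x)
}

#' Re-fit the passive pitch-down transfer function to a pitch series
#'
#' Least-squares fit of the free coefficients of the fifth-order structure
#' `(b2 s^2 + b1 s) / (s^2 (a3 s^3 + a2 s^2 + a1 s + 1))` to a pre-onset
#' pitch time series (the response to a step of amplitude -pi/2), starting
#' from the canonical [tf_passive_pitch()] coefficients.
#'
#' @param t time vector (s), uniform at `Ts` starting at 0.
#' @param pitch observed pitch series (rad).
#' @param Ts sample period (s).
#' @return list with `coef` (named: `b2`, `b1`, `a3`, `a2`, `a1`), `rms`
#'   residual (rad), `fitted` series, `converged` and `degenerate` flags.
#' @export
fit_passive_tf <- function(t, pitch, Ts = 1 / 1600) {
  stopifnot(length(t) == length(pitch), length(t) >= 10)
  if (all(abs(pitch) < 1e-12)) {
    warning("degenerate input: constant-zero pitch series")
    return(list(coef = c(b2 = NA, b1 = NA, a3 = NA, a2 = NA, a1 = NA),
                rms = NA_real_, fitted = rep(0, length(t)),
                converged = FALSE, degenerate = TRUE))
  }
  n <- length(t)
  # canonical coefficients differ by 4 orders of magnitude; optimize
  # multiplicative corrections so the search space is well scaled
  start <- c(b2 = 0.001, b1 = 30, a3 = 0.0011, a2 = 0.0005, a1 = 0.01)
  model <- function(theta) {
    p <- start * theta
    den <- .polymul(c(1, 0, 0), c(p["a3"], p["a2"], p["a1"], 1))
    blk <- try(discretize_lti(lti_tf(c(p["b2"], p["b1"], 0), den), Ts = Ts),
               silent = TRUE)
    if (inherits(blk, "try-error")) return(rep(1e6, n))
    y <- lti_filter(blk, rep(-pi / 2, n))
    y[!is.finite(y)] <- 1e6
    y
  }
  fit <- minpack.lm::nls.lm(par = setNames(rep(1, 5), names(start)),
                            fn = function(theta) model(theta) - pitch,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400, ftol = 1e-14, ptol = 1e-14))
  cf <- start * fit$par
  fitted <- model(fit$par)
  rms <- sqrt(mean((fitted - pitch)^2))
  converged <- fit$info %in% 1:4
  if (!converged) warning("passive transfer-function fit did not converge")
  list(coef = cf, rms = rms, fitted = fitted, converged = converged,
       degenerate = FALSE)
}
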