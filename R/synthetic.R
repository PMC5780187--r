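# Synthetic pseudo-experimental cohorts: simulated falls converted to
# noisy 3-D landmark tables with the statistical structure the analysis
# stages assume (onset distribution, pitch and position measurement noise,
# a controllable fraction of non-recovering trials), plus a truth sidecar.

#' Specification of a synthetic cohort
#'
#' @param n_trials number of falls.
#' @param gains generating [controller_gains()].
#' @param onset_dist `"lognormal"` (truncated, implied mean 103 ms) or
#'   `"uniform"` on the onset window.
#' @param pitch_noise_sd per-frame pitch measurement noise (rad); default
#'   the 0.08 rad (about 5 degrees) error of the stereo pitch estimation.
#' @param pos_noise_sd landmark position noise (m); default 0.5 mm,
#'   sub-millimetre as in the quantization analysis.
#' @param nonrecovering_frac fraction of trials built to fail the trial
#'   selection filter (late wingbeats or no force).
#' @param variant model variant driving the trials.
#' @param seed RNG seed.
#' @return list of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_trials = 57, gains = controller_gains(),
                              onset_dist = c("lognormal", "uniform"),
                              pitch_noise_sd = 0.08, pos_noise_sd = 5e-4,
                              nonrecovering_frac = 0,
                              variant = "improved", seed = 1) {
  onset_dist <- match.arg(onset_dist)
  stopifnot(n_trials >= 1, pitch_noise_sd >= 0, pos_noise_sd >= 0,
            nonrecovering_frac >= 0, nonrecovering_frac < 1)
  structure(list(n_trials = n_trials, gains = gains,
                 onset_dist = onset_dist, pitch_noise_sd = pitch_noise_sd,
                 pos_noise_sd = pos_noise_sd,
                 nonrecovering_frac = nonrecovering_frac,
                 variant = variant, seed = seed),
            class = "synth_cohort_spec")
}

#' Draw wingbeat-onset times
#'
#' `"uniform"` draws from the onset window.  `"lognormal"` draws from a
#' lognormal with log-sd 0.28 whose location is solved (numerically, on
#' the truncated distribution) so the truncated mean equals `mean_target`;
#' draws outside `trunc` are resampled.
#'
#' @param n number of draws.
#' @param distribution `"uniform"` or `"lognormal"`.
#' @param window uniform sampling window (s).
#' @param mean_target target mean of the truncated lognormal (s).
#' @param sdlog lognormal log-domain sd.
#' @param trunc truncation interval for the lognormal (s).
#' @return onset times (s).
#' @export
generate_onsets <- function(n, distribution = c("uniform", "lognormal"),
                            window = c(0.075, 0.150), mean_target = 0.103,
                            sdlog = 0.28, trunc = c(0.060, 0.180)) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1)
  if (distribution == "uniform")
    return(runif(n, window[1], window[2]))
  mu <- .lognormal_trunc_location(mean_target, sdlog, trunc)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(n, meanlog = mu, sdlog = sdlog)
    out <- c(out, draw[draw >= trunc[1] & draw <= trunc[2]])
  }
  out[seq_len(n)]
}

# location parameter such that the truncated-lognormal mean hits `target`
.lognormal_trunc_location <- function(target, sdlog, trunc) {
  tmean <- function(mu) {
    # E[X | a <= X <= b] for X ~ lognormal(mu, sdlog)
    a <- (log(trunc[1]) - mu) / sdlog
    b <- (log(trunc[2]) - mu) / sdlog
    num <- pnorm(b - sdlog) - pnorm(a - sdlog)
    den <- pnorm(b) - pnorm(a)
    exp(mu + sdlog^2 / 2) * num / den
  }
  uniroot(function(mu) tmean(mu) - target,
          interval = log(target) + c(-1, 1), tol = 1e-12)$root
}

#' Generate a synthetic pseudo-experimental cohort
#'
#' Runs the flight simulator for each trial, converts the planar states to
#' 3-D (a small constant lateral drift stands in for the shallow
#' out-of-plane motion of real falls), and synthesizes head/centroid/tail
#' landmarks on the body axis: the axis is tilted by the per-frame pitch
#' measurement noise, head and tail sit half a body length (body length
#' uniform in 10-15 mm) from the centroid, and every landmark coordinate
#' receives Gaussian position noise.  Non-recovering trials are produced
#' by delaying the wingbeat onset beyond the selection threshold or by
#' zeroing the force loop (alternating, to exercise both selection
#' clauses).
#'
#' @param spec a [synth_cohort_spec()].
#' @param config a [sim_config()].
#' @param horizon simulation length per trial (s).
#' @return list of class `synth_cohort` with `trials` (each: `raw`, a
#'   landmark data.frame with columns `t`, `head_x` ... `tail_z`;
#'   `trajectory`, the underlying `fall_trajectory`) and `truth` (spec,
#'   per-trial onset, body length, mechanism, crash label, generating
#'   gains).
#' @export
generate_cohort <- function(spec = synth_cohort_spec(),
                            config = sim_config(), horizon = 0.5) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_trials
  n_bad <- round(spec$nonrecovering_frac * n)
  onsets <- generate_onsets(n, spec$onset_dist,
                            window = config$onset_window)
  bad_idx <- if (n_bad > 0) sample.int(n, n_bad) else integer(0)
  mechanisms <- rep("recovering", n)
  if (n_bad > 0)
    mechanisms[bad_idx] <- rep(c("late_onset", "no_force"),
                               length.out = n_bad)
  trials <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    onset_i <- onsets[i]
    gains_i <- spec$gains
    if (mechanisms[i] == "late_onset")
      onset_i <- runif(1, 0.155, 0.180)
    if (mechanisms[i] == "no_force")   # wingbeats trigger but produce no force
      gains_i <- do.call(controller_gains,
                         modifyList(unclass(gains_i),
                                    list(Kp_wz = 0, Ki_wz = 0)))
    tr <- simulate_fall(config, gains_i, onset = onset_i,
                        variant = spec$variant, horizon = horizon,
                        force_scale =
                          if (mechanisms[i] == "no_force") 0 else 1)
    s <- tr$states
    vy <- runif(1, -0.05, 0.05)            # slow lateral drift
    body_len <- runif(1, 0.010, 0.015)
    theta_tilde <- s$theta_p + rnorm(nrow(s), 0, spec$pitch_noise_sd)
    axis <- cbind(cos(theta_tilde), 0, sin(theta_tilde))
    centroid <- cbind(s$x, vy * s$t, s$z)
    noise <- function() matrix(rnorm(3 * nrow(s), 0, spec$pos_noise_sd),
                               ncol = 3)
    head_m <- centroid + body_len / 2 * axis + noise()
    cent_m <- centroid + noise()
    tail_m <- centroid - body_len / 2 * axis + noise()
    raw <- data.frame(t = s$t,
                      head_x = head_m[, 1], head_y = head_m[, 2],
                      head_z = head_m[, 3],
                      centroid_x = cent_m[, 1], centroid_y = cent_m[, 2],
                      centroid_z = cent_m[, 3],
                      tail_x = tail_m[, 1], tail_y = tail_m[, 2],
                      tail_z = tail_m[, 3])
    trials[[i]] <- list(raw = raw, trajectory = tr)
    truth_rows[[i]] <- data.frame(trial = i, onset = tr$onset,
                                  body_length = body_len,
                                  mechanism = mechanisms[i],
                                  crashed = tr$crashed)
  }
  structure(list(trials = trials,
                 truth = list(spec = spec,
                              gains = spec$gains,
                              trials = do.call(rbind, truth_rows))),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  tt <- x$truth$trials
  cat(sprintf("<synth_cohort: %d trials (%d non-recovering by design)>\n",
              nrow(tt), sum(tt$mechanism != "recovering")))
  invisible(x)
}

#' Observed pitch series from a synthetic cohort
#'
#' Reconstructs the pitch of each trial from its noisy landmarks via
#' [pitch_from_landmarks()] and packages it with the truth onset, in the
#' form [trajectory_loglik()] and [mle_grid()] accept.
#'
#' @param cohort a `synth_cohort`.
#' @param min_window if non-`NULL`, drop trials whose post-onset series is
#'   shorter than this many seconds (trials that crashed or diverged early
#'   cannot be compared over the identification window, mirroring the
#'   study's restriction to recovering falls).
#' @return list of observed-pitch lists (`onset`, `t`, `theta_p`).
#' @export
cohort_observed_pitch <- function(cohort, min_window = NULL) {
  stopifnot(inherits(cohort, "synth_cohort"))
  tt <- cohort$truth$trials
  obs <- lapply(seq_along(cohort$trials), function(i) {
    raw <- cohort$trials[[i]]$raw
    post <- raw$t >= tt$onset[i]
    est <- pitch_from_landmarks(raw[post, ])
    list(onset = tt$onset[i], t = raw$t[post], theta_p = est$pitch)
  })
  if (!is.null(min_window)) {
    Ts <- diff(cohort$trials[[1]]$raw$t[1:2])
    obs <- Filter(function(o)
      length(o$theta_p) >= as.integer(round(min_window / Ts)), obs)
  }
  obs
}
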