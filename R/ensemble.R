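# Randomized ensembles of simulated free falls and their summary statistics:
# onset-group-aligned means, settling times, instability onsets, crash
# fractions and onset-distribution fits.

.onset_group_breaks <- c(0.075, 0.100, 0.125, 0.150)
.onset_group_labels <- c("75-100ms", "100-125ms", "125-150ms")

#' Run an ensemble of simulated free falls
#'
#' Simulates `n` independent falls with wingbeat-onset times drawn from the
#' configured window and summarizes them: onset groups (75-100, 100-125,
#' 125-150 ms), onset-aligned per-group mean time series, crash fraction,
#' per-group settling times of the mean pitch, and per-trajectory
#' instability onsets.  Deterministic given `seed`.
#'
#' @param n number of falls.
#' @param config a [sim_config()].
#' @param gains a [controller_gains()].
#' @param variant `"basic"` or `"improved"`.
#' @param seed RNG seed.
#' @param horizon simulation length per fall (s).
#' @param onset_dist `"uniform"` on the onset window, or `"lognormal"`
#'   (truncated, implied mean 103 ms; see [generate_onsets()]).
#' @param stop_at_floor passed to [simulate_fall()].
#' @return an object of class `fall_ensemble`: list with `trajectories`,
#'   `onsets`, `groups` (factor), `group_means` (named list of data.frames
#'   with onset-aligned columns `t_rel`, `theta_p`, `omega_x`, `omega_z`,
#'   `z`, `vz`, `vx`, `n_contrib`), `crash_fraction`, `settling` (s, per
#'   group), `instability_onsets` (s, per trajectory, `NA` if none),
#'   `variant`, `seed`.
#' @export
run_ensemble <- function(n, config = sim_config(), gains = controller_gains(),
                         variant = c("basic", "improved"), seed = 1,
                         horizon = 3, onset_dist = c("uniform", "lognormal"),
                         stop_at_floor = TRUE) {
  stopifnot(n >= 1)
  variant <- match.arg(variant)
  onset_dist <- match.arg(onset_dist)
  set.seed(seed)
  onsets <- generate_onsets(n, distribution = onset_dist,
                            window = config$onset_window)
  trajectories <- lapply(onsets, function(on)
    simulate_fall(config, gains, onset = on, variant = variant,
                  horizon = horizon, stop_at_floor = stop_at_floor))
  groups <- cut(onsets, breaks = .onset_group_breaks,
                labels = .onset_group_labels, include.lowest = TRUE,
                right = FALSE)
  group_means <- ensemble_group_means(trajectories, groups)
  crashed <- vapply(trajectories, function(tr) tr$crashed, logical(1))
  settling <- vapply(group_means, function(gm) {
    if (is.null(gm)) return(NA_real_)
    settling_time(gm$t_rel, gm$theta_p)
  }, numeric(1))
  inst <- vapply(trajectories, function(tr)
    instability_onset(tr), numeric(1))
  structure(list(trajectories = trajectories, onsets = onsets,
                 groups = groups, group_means = group_means,
                 crash_fraction = mean(crashed), settling = settling,
                 instability_onsets = inst, variant = variant,
                 seed = seed, horizon = horizon),
            class = "fall_ensemble")
}

#' @export
print.fall_ensemble <- function(x, ...) {
  cat(sprintf("<fall_ensemble: %d %s-model falls, horizon %.1f s>\n",
              length(x$trajectories), x$variant, x$horizon))
  cat(sprintf("  crash fraction: %.3f\n", x$crash_fraction))
  cat("  settling time of mean pitch (ms):",
      paste(sprintf("%s=%s", names(x$settling),
                    ifelse(is.na(x$settling), "never",
                           sprintf("%.0f", 1000 * x$settling))),
            collapse = ", "), "\n")
  if (any(!is.na(x$instability_onsets)))
    cat(sprintf("  median instability onset: %.3f s\n",
                median(x$instability_onsets, na.rm = TRUE)))
  invisible(x)
}

#' Onset-aligned per-group mean time series
#'
#' Aligns every trajectory of a group at its wingbeat-onset sample and
#' averages sample-wise.  Series are truncated at the shortest member of
#' the group; groups with fewer than two members yield `NULL` (means are
#' only reported where at least two trajectories contribute).
#'
#' @param trajectories list of `fall_trajectory`.
#' @param groups factor of group memberships (same length).
#' @return named list (one per group level) of data.frames with columns
#'   `t_rel` (s after onset), `theta_p`, `omega_x`, `omega_z`, `z`, `vz`,
#'   `vx`, `n_contrib`.
#' @export
ensemble_group_means <- function(trajectories, groups) {
  cols <- c("theta_p", "omega_x", "omega_z", "z", "vz", "vx")
  out <- lapply(levels(groups), function(lev) {
    members <- trajectories[which(groups == lev)]
    if (length(members) < 2) return(NULL)
    post <- lapply(members, function(tr) tr$states[tr$states$t >= tr$onset, ])
    len <- min(vapply(post, nrow, integer(1)))
    if (len < 1) return(NULL)
    Ts <- members[[1]]$config$Ts
    df <- data.frame(t_rel = (seq_len(len) - 1) * Ts)
    for (cn in cols) {
      m <- vapply(post, function(p) p[[cn]][seq_len(len)], numeric(len))
      df[[cn]] <- rowMeans(m)
    }
    df$n_contrib <- length(members)
    df
  })
  names(out) <- levels(groups)
  out
}

#' Settling time of a signal into a band around its final value
#'
#' First time after `onset` from which the signal stays within `band` of
#' its final value for the remainder of the window.
#'
#' @param t time vector (s).
#' @param x signal vector.
#' @param onset reference time subtracted from the result; defaults to the
#'   first time point.
#' @param band half-width of the settling band (same units as `x`).
#' @return settling time in seconds after `onset`; 0 if the signal never
#'   leaves the band; `NA` if it never enters it.
#' @export
settling_time <- function(t, x, onset = t[1], band = 0.1) {
  stopifnot(length(t) == length(x), length(t) >= 1)
  ref <- x[length(x)]
  bad <- which(abs(x - ref) > band)
  if (length(bad) == 0) return(0)
  if (max(bad) == length(x)) return(NA_real_)
  t[max(bad) + 1L] - onset
}

#' Detect the onset of closed-loop instability
#'
#' Operationalizes "highly unstable": the first time, measured from the
#' start of the fall, at which either |pitch| exceeds pi/2 or the absolute
#' forward-OF error exceeds `mult` times its value at wingbeat onset.  A
#' trajectory that triggered the divergence guard without crossing either
#' threshold reports its truncation time.
#'
#' @param traj a `fall_trajectory`.
#' @param mult OF-error growth multiplier (default 10).
#' @return time in seconds, or `NA` if the trajectory never destabilizes.
#' @export
instability_onset <- function(traj, mult = 10) {
  s <- traj$states
  sp <- traj$gains$omega_x_setpoint
  post <- s$t >= traj$onset
  err <- abs(-s$omega_x - sp)            # forward-OF error, projection conv.
  ref <- err[which(post)[1]]
  hit <- which((abs(s$theta_p) > pi / 2) | (post & err > mult * ref))
  if (length(hit) > 0) return(s$t[hit[1]])
  if (traj$diverged) return(s$t[nrow(s)])
  NA_real_
}

#' Select trials the way the experimental analysis did
#'
#' Keeps trajectories whose wingbeat onset came within 150 ms of release
#' and that reached a positive vertical speed within the 300 ms analysis
#' window after onset; each kept trajectory is truncated at its first
#' positive-vz instant, or at onset + 300 ms, whichever comes first.
#'
#' @param trajectories list of `fall_trajectory`.
#' @param onset_max onset threshold (s).
#' @param window analysis window after onset (s).
#' @return list with `selected` (truncated trajectories), `index` (their
#'   positions in the input), `n_in`, `n_kept`.
#' @export
select_trials <- function(trajectories, onset_max = 0.150, window = 0.300) {
  keep <- logical(length(trajectories))
  selected <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    if (tr$onset >= onset_max) next
    s <- tr$states
    post <- which(s$t >= tr$onset & s$t <= tr$onset + window)
    pos <- post[s$vz[post] > 0]
    if (length(pos) == 0) next
    keep[i] <- TRUE
    tr$states <- s[s$t <= s$t[pos[1]], ]
    selected[[i]] <- tr
  }
  list(selected = selected[keep], index = which(keep),
       n_in = length(trajectories), n_kept = sum(keep))
}

#' Fit normal and lognormal distributions to wingbeat-onset times
#'
#' Closed-form maximum-likelihood fits; the lognormal is fitted in the log
#' domain and both implied means are reported (the experimental onset
#' histogram is nearly symmetric, so the two means agree closely).
#'
#' @param onsets onset times (s or ms, any consistent unit), at least 5.
#' @return list with `normal` (`mean`, `sd`), `lognormal` (`meanlog`,
#'   `sdlog`, `mean`), and `degenerate` (`TRUE` when the sample variance is
#'   zero).
#' @export
fit_onset_distribution <- function(onsets) {
  if (length(onsets) < 5) stop("need at least 5 onset times")
  if (any(onsets <= 0)) stop("non-positive onsets not admissible under a lognormal")
  n <- length(onsets)
  mu <- mean(onsets)
  s2 <- mean((onsets - mu)^2)            # MLE (1/n) variance
  lx <- log(onsets)
  ml <- mean(lx)
  sl <- sqrt(mean((lx - ml)^2))
  list(normal = list(mean = mu, sd = sqrt(s2)),
       lognormal = list(meanlog = ml, sdlog = sl,
                        mean = exp(ml + sl^2 / 2)),
       degenerate = s2 == 0)
}
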