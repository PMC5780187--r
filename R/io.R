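# Configuration files and on-disk formats.  Everything tabular is CSV with
# a header row; metadata and metrics travel as JSON sidecars; run
# configurations are YAML.  No binary formats: the datasets are tiny.

.run_config_fields <- c("sim", "gains", "variant", "n", "seed", "horizon",
                        "onset_dist")

#' Load a run configuration
#'
#' Reads a YAML file with optional sections `sim` (fields of
#' [sim_config()]), `gains` (fields of [controller_gains()]) and top-level
#' keys `variant`, `n`, `seed`, `horizon`, `onset_dist`.  Omitted fields
#' take the study defaults (Ts = 1/1600 s, d_wall = 0.20 m, g = 9.81,
#' KpH = 7, KiH = 0.3, OF setpoint 0.04, ...); unknown keys are rejected.
#' An empty (or missing-section) file therefore yields the full default
#' configuration.
#'
#' @param path YAML file path.
#' @return list of class `run_config` with elements `config`
#'   (a `sim_config`), `gains` (a `controller_gains`), `variant`, `n`,
#'   `seed`, `horizon`, `onset_dist`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .run_config_fields)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  check_section <- function(sec, allowed) {
    bad <- setdiff(names(sec), allowed)
    if (length(bad) > 0)
      stop("unknown keys: ", paste(bad, collapse = ", "))
    sec
  }
  sim_args <- check_section(raw$sim, names(formals(sim_config)))
  gain_args <- check_section(raw$gains, names(formals(controller_gains)))
  if (!is.null(sim_args$onset_window))
    sim_args$onset_window <- as.numeric(sim_args$onset_window)
  cfg <- do.call(sim_config, as.list(sim_args))
  gn <- do.call(controller_gains, as.list(gain_args))
  variant <- raw$variant %||% "basic"
  if (!variant %in% c("basic", "improved"))
    stop("variant must be 'basic' or 'improved'")
  structure(list(config = cfg, gains = gn, variant = variant,
                 n = as.integer(raw$n %||% 1L),
                 seed = as.integer(raw$seed %||% 1L),
                 horizon = as.numeric(raw$horizon %||% cfg$horizon),
                 onset_dist = raw$onset_dist %||% "uniform"),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes YAML that [load_config()] reads back to an identical object.
#'
#' @param rc a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  sim <- unclass(rc$config)
  sim$seed <- NULL
  out <- list(sim = sim, gains = unclass(rc$gains), variant = rc$variant,
              n = rc$n, seed = rc$seed, horizon = rc$horizon,
              onset_dist = rc$onset_dist)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a simulated trajectory to CSV with a JSON metadata sidecar
#'
#' The CSV holds the per-sample states (`t, x, z, vx, vz, theta_p,
#' theta_p_dot, F_mag, L, T, omega_x, omega_z`); the sidecar
#' (`<path>.meta.json`) records variant, onset, crash/divergence flags,
#' configuration and gains.
#'
#' @param traj a `fall_trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_fall_csv <- function(traj, path) {
  stopifnot(inherits(traj, "fall_trajectory"))
  write.csv(traj$states, path, row.names = FALSE)
  meta <- list(variant = traj$variant, onset = traj$onset,
               crashed = traj$crashed, crash_time = traj$crash_time,
               diverged = traj$diverged,
               config = unclass(traj$config), gains = unclass(traj$gains))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_fall_csv()]
#'
#' @param path CSV path (the `.meta.json` sidecar must sit next to it).
#' @return a `fall_trajectory`.
#' @export
read_fall_csv <- function(path) {
  states <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  cfg$seed <- cfg$seed %||% NULL
  config <- sim_config(d_wall = cfg$d_wall, box_height = cfg$box_height,
                       g = cfg$g, Ts = cfg$Ts,
                       onset_window = as.numeric(cfg$onset_window),
                       horizon = cfg$horizon, seed = cfg$seed)
  gains <- do.call(controller_gains, as.list(meta$gains))
  structure(list(states = states, onset = meta$onset,
                 variant = meta$variant, crashed = meta$crashed,
                 crash_time = meta$crash_time %||% NA_real_,
                 diverged = meta$diverged, config = config, gains = gains),
            class = "fall_trajectory")
}

#' Write a synthetic cohort as landmark CSVs plus a truth sidecar
#'
#' One `trial_###.csv` per trial (columns `t`, `head_x` ... `tail_z`) and
#' a `truth.json` holding the generating spec, gains and per-trial labels
#' -- sufficient to recompute crash and selection labels independently.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$trials))
    write.csv(cohort$trials[[i]]$raw,
              file.path(dir, sprintf("trial_%03d.csv", i)),
              row.names = FALSE)
  truth <- cohort$truth
  truth$spec$gains <- unclass(truth$spec$gains)
  truth$spec <- unclass(truth$spec)
  truth$gains <- unclass(truth$gains)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read the landmark tables of a cohort directory
#'
#' @param dir directory written by [write_cohort()].
#' @return list with `raw` (list of landmark data.frames) and `truth`.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no trial CSVs in ", dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(raw = lapply(files, read.csv), truth = truth)
}

#' Write summary metrics as JSON
#'
#' @param metrics named list of scalar metrics or small structures.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
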