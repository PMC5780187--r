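# Experimental-data computations: accelerations and wing force from 3-D
# positions, body-axis orientation from tracked landmarks, theoretical
# optic flow from measured speeds, and stereo-rig metrology.

#' Acceleration and wing-force magnitude from 3-D positions
#'
#' Double-differentiates tracked positions by central differences, smooths
#' the result with a Savitzky-Golay filter (order 1, frame length 11), and
#' recovers the mass-normalized wing force as
#' `|F| = sqrt(Axy^2 + (Az - g)^2)` with `g = -9.81` (gravity subtracted
#' from the vertical acceleration).  The first and last 6 samples (one for
#' the difference stencil, five for the filter half-window) are edge
#' effects and returned as `NA`.
#'
#' @param positions matrix or data.frame with columns `x`, `y`, `z` (m),
#'   uniformly sampled; at least 13 rows.
#' @param Ts sample period (s).
#' @param g signed gravitational acceleration (m/s^2, z up).
#' @param sg_order,sg_length Savitzky-Golay polynomial order and frame
#'   length.
#' @return data.frame with columns `Ax`, `Ay`, `Az`, `Axy`, `F_mag`
#'   (m/s^2), same number of rows as `positions`.
#' @export
accel_from_positions <- function(positions, Ts = 1 / 1600, g = -9.81,
                                 sg_order = 1, sg_length = 11) {
  pos <- as.data.frame(positions)
  stopifnot(all(c("x", "y", "z") %in% names(pos)))
  n <- nrow(pos)
  if (n < sg_length + 2)
    stop("need at least ", sg_length + 2, " samples (filter length + stencil)")
  ddiff <- function(p) {
    a <- rep(NA_real_, n)
    k <- 2:(n - 1)
    a[k] <- (p[k + 1] - 2 * p[k] + p[k - 1]) / Ts^2
    inner <- signal::sgolayfilt(a[k], p = sg_order, n = sg_length)
    a[k] <- inner
    half <- (sg_length - 1) / 2
    a[seq_len(1 + half)] <- NA
    a[(n - half):n] <- NA
    a
  }
  Ax <- ddiff(pos$x)
  Ay <- ddiff(pos$y)
  Az <- ddiff(pos$z)
  Axy <- sqrt(Ax^2 + Ay^2)
  data.frame(Ax = Ax, Ay = Ay, Az = Az, Axy = Axy,
             F_mag = sqrt(Axy^2 + (Az - g)^2))
}

#' Body yaw and pitch from tracked landmark clouds
#'
#' Two successive linear regressions, as in the tracking pipeline: the yaw
#' of the main body axis is estimated by regression in the XY plane, the
#' cloud is counter-rotated to align that axis with X, and the pitch is
#' estimated by regression in the ZX plane.  The axis direction (head vs
#' tail) disambiguates the yaw; pitch falls in [-pi/2, pi/2].  Clouds that
#' are degenerate in the XY projection (near-vertical) fall back to the
#' principal-component axis and are flagged.
#'
#' @param head,centroid,tail landmark coordinates: numeric length-3
#'   vectors, or matrices with columns x, y, z holding replicate points
#'   (e.g. one row per binarization threshold).
#' @return list with `yaw` (rad), `pitch` (rad), `method`
#'   (`"regression"` or `"pca"`).
#' @export
body_axis_pitch <- function(head, centroid, tail) {
  as_mat <- function(p) {
    m <- if (is.null(dim(p))) matrix(p, nrow = 1) else as.matrix(p)
    stopifnot(ncol(m) == 3)
    m
  }
  h <- as_mat(head); cen <- as_mat(centroid); tl <- as_mat(tail)
  cloud <- rbind(h, cen, tl)
  dir_ht <- colMeans(h) - colMeans(tl)     # orients the axis head-ward
  if (sum(dir_ht[1:2]^2) < .Machine$double.eps)
    dir_ht[1:2] <- c(1, 0)
  x <- cloud[, 1]; y <- cloud[, 2]; z <- cloud[, 3]
  method <- "regression"
  vx <- var(x)
  if (vx > 1e-16 * max(var(y), 1e-30) && vx > 0) {
    slope <- coef(lm(y ~ x))[2]
    if (!is.finite(slope)) slope <- 0
    yaw <- atan(slope)
  } else {
    method <- "pca"
    pc <- prcomp(cloud[, 1:2])$rotation[, 1]
    yaw <- atan2(pc[2], pc[1])
  }
  # orient toward the head
  if (cos(yaw) * dir_ht[1] + sin(yaw) * dir_ht[2] < 0) yaw <- yaw + pi
  yaw <- atan2(sin(yaw), cos(yaw))
  xr <- x * cos(yaw) + y * sin(yaw)
  if (var(xr) > 0) {
    slope_z <- coef(lm(z ~ xr))[2]
    if (!is.finite(slope_z)) slope_z <- 0
    pitch <- atan(slope_z)
  } else {
    pitch <- sign(dir_ht[3]) * pi / 2
  }
  list(yaw = unname(yaw), pitch = unname(pitch), method = method)
}

#' Pitch series from tracked head/centroid/tail landmarks
#'
#' Applies [body_axis_pitch()] frame-by-frame to a landmark table.
#'
#' @param raw data.frame with columns `head_x`, `head_y`, `head_z`,
#'   `centroid_x`, ..., `tail_z` (one row per frame).
#' @return data.frame with columns `yaw` and `pitch` (rad).
#' @export
pitch_from_landmarks <- function(raw) {
  need <- as.vector(outer(c("head", "centroid", "tail"),
                          c("x", "y", "z"), paste, sep = "_"))
  stopifnot(all(need %in% names(raw)))
  out <- t(vapply(seq_len(nrow(raw)), function(i) {
    r <- body_axis_pitch(
      as.numeric(raw[i, c("head_x", "head_y", "head_z")]),
      as.numeric(raw[i, c("centroid_x", "centroid_y", "centroid_z")]),
      as.numeric(raw[i, c("tail_x", "tail_y", "tail_z")]))
    c(r$yaw, r$pitch)
  }, numeric(2)))
  data.frame(yaw = out[, 1], pitch = out[, 2])
}

#' Theoretical optic flow from measured speeds and wall distances
#'
#' The OF vector is the opposite of the instantaneous speed vector divided
#' by the distance to the lateral walls; of the two resulting vectors only
#' the one with the maximal norm (nearest wall) is kept.
#'
#' @param vx,vz velocity components (m/s).
#' @param theta_p measured pitch (rad).
#' @param d_left,d_right distances to the two lateral walls (m), positive.
#' @return data.frame as returned by [optic_flow()].
#' @export
theoretical_of <- function(vx, vz, theta_p, d_left, d_right) {
  if (any(d_left <= 0) || any(d_right <= 0))
    stop("wall distances must be > 0")
  optic_flow(vx, vz, theta_p, d_wall = pmin(d_left, d_right))
}

#' Stereo rig description
#'
#' Defaults are the study's rig: 25.6 mm sensor width, 333.5 mm baseline,
#' 1280 px image width, 30 mm focal length.
#'
#' @param SW sensor width (mm).
#' @param BL baseline between the two (virtual) cameras (mm).
#' @param IW image width (pixels).
#' @param FL focal length (mm).
#' @return list of class `stereo_rig`.
#' @export
stereo_rig <- function(SW = 25.6, BL = 333.5, IW = 1280, FL = 30) {
  vals <- c(SW = SW, BL = BL, IW = IW, FL = FL)
  if (any(vals <= 0)) stop("all rig parameters must be strictly positive")
  structure(as.list(vals), class = "stereo_rig")
}

#' Minimal resolvable distance of a stereo rig
#'
#' `delta_d = d^2 SW / (BL IW FL)`: the smallest distance between two
#' points that the stereo reconstruction can tell apart at object distance
#' `d`.
#'
#' @param d object distance (mm); vectorized.
#' @param rig a [stereo_rig()].
#' @return minimal resolvable distance (mm).
#' @export
stereo_min_distance <- function(d, rig = stereo_rig()) {
  stopifnot(all(d > 0))
  d^2 * rig$SW / (rig$BL * rig$IW * rig$FL)
}

#' Quantization positional uncertainty
#'
#' RMS position error induced by pixel quantization,
#' `QPU_rms = sqrt(delta_d^2 / 12) = delta_d / sqrt(12)`.
#'
#' @param delta_d minimal resolvable distance (mm), non-negative.
#' @return RMS uncertainty (mm).
#' @export
quantization_uncertainty <- function(delta_d) {
  stopifnot(all(delta_d >= 0))
  delta_d / sqrt(12)
}

#' Spatial frequency of a square-wave grating
#'
#' One cycle is a black plus a white stripe; the frequency is the inverse
#' of the angle (in degrees, exact arctangent) subtended by one cycle at
#' the viewing distance.
#'
#' @param stripe_width width of one stripe (m).
#' @param distance viewing distance (m).
#' @return spatial frequency in cycles per degree.
#' @export
grating_spatial_frequency <- function(stripe_width, distance) {
  stopifnot(all(stripe_width > 0), all(distance > 0))
  cycle <- 2 * stripe_width
  angle_deg <- 2 * atan(cycle / (2 * distance)) * 180 / pi
  1 / angle_deg
}
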