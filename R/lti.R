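# Continuous-time transfer functions and their fixed-step discretization.
#
# All dynamic blocks of the flight model (wing-force filter, passive pitch,
# controllers, actuator lag) are rational transfer functions in the Laplace
# variable s, simulated at the camera frame period Ts = 1/1600 s after a
# bilinear (Tustin) transform.  Coefficient vectors are in descending powers
# of s (resp. z), as in signal/Octave.

.polytrim <- function(p) {
  nz <- which(p != 0)
  if (length(nz) == 0) return(0)
  p[nz[1]:length(p)]
}

.polyadd <- function(p, q) {
  n <- max(length(p), length(q))
  c(rep(0, n - length(p)), p) + c(rep(0, n - length(q)), q)
}

.polymul <- function(p, q) {
  convolve(p, rev(q), type = "open")
}

.polypow <- function(p, k) {
  out <- 1
  while (k > 0) {
    out <- .polymul(out, p)
    k <- k - 1
  }
  out
}

#' Continuous-time transfer function
#'
#' Light container for a rational transfer function `num(s)/den(s)`.
#' Numerator order may exceed the denominator order by at most one (a single
#' pure differentiator survives the bilinear transform as the trapezoid
#' differencer); anything more improper is rejected.
#'
#' @param num numerator coefficients, descending powers of s.
#' @param den denominator coefficients, descending powers of s; the leading
#'   coefficient must be nonzero.
#' @return an object of class `lti_tf`.
#' @export
lti_tf <- function(num, den) {
  stopifnot(is.numeric(num), is.numeric(den))
  den <- .polytrim(den)
  num <- .polytrim(num)
  if (abs(den[1]) <= .Machine$double.eps)
    stop("denominator leading coefficient must be nonzero")
  if (length(num) > length(den) + 1)
    stop("improper system beyond one differentiator: numerator order ",
         length(num) - 1, " vs denominator order ", length(den) - 1)
  structure(list(num = num, den = den), class = "lti_tf")
}

#' @export
print.lti_tf <- function(x, ...) {
  cat("Continuous transfer function\n")
  cat("  num:", signif(x$num, 6), "\n")
  cat("  den:", signif(x$den, 6), "\n")
  invisible(x)
}

#' DC gain of a transfer function
#'
#' Ratio of the constant coefficients; `Inf` for blocks with free
#' integrators, 0 for pure differentiators.
#'
#' @param tf an `lti_tf`.
#' @return scalar gain (possibly infinite).
#' @export
dc_gain <- function(tf) {
  b0 <- tf$num[length(tf$num)]
  a0 <- tf$den[length(tf$den)]
  if (a0 == 0) return(if (b0 == 0) NA_real_ else Inf * sign(b0))
  b0 / a0
}

#' Discretize a transfer function with the bilinear (Tustin) transform
#'
#' Substitutes `s = (2/Ts)(z-1)/(z+1)` and multiplies through by
#' `(z+1)^n`, where n is the larger of the numerator and denominator
#' orders.  The transform preserves the DC gain and maps the open left half
#' plane into the unit disc, so stable blocks stay stable at any step size.
#'
#' @param num,den continuous coefficients (descending powers of s), or pass
#'   an `lti_tf` as `num`.
#' @param Ts sample period in seconds.
#' @return an object of class `lti_block` with fields `b`, `a` (discrete
#'   coefficients in powers of z^-1), `Ts`, and the source `num`, `den`.
#' @export
discretize_lti <- function(num, den = NULL, Ts) {
  if (inherits(num, "lti_tf")) {
    tf <- num
  } else {
    tf <- lti_tf(num, den)
  }
  stopifnot(is.numeric(Ts), length(Ts) == 1, Ts > 0)
  n <- max(length(tf$num), length(tf$den)) - 1
  k2 <- 2 / Ts
  expand <- function(coefs) {
    out <- 0
    for (j in seq_along(coefs)) {
      k <- length(coefs) - j                   # power of s carried by coefs[j]
      term <- coefs[j] * k2^k *
        .polymul(.polypow(c(1, -1), k), .polypow(c(1, 1), n - k))
      out <- .polyadd(out, term)
    }
    out
  }
  b <- expand(tf$num)
  a <- expand(tf$den)
  b <- c(rep(0, length(a) - length(b)), b)
  b <- b / a[1]
  a <- a / a[1]
  structure(list(b = b, a = a, Ts = Ts, num = tf$num, den = tf$den),
            class = "lti_block")
}

#' @export
print.lti_block <- function(x, ...) {
  cat("Discrete LTI block (Tustin, Ts =", x$Ts, "s)\n")
  cat("  b:", signif(x$b, 6), "\n")
  cat("  a:", signif(x$a, 6), "\n")
  invisible(x)
}

#' Run a discrete LTI block over an input sequence
#'
#' Zero initial state; uniform sampling at the block's `Ts`.
#'
#' @param block an `lti_block`.
#' @param u numeric input sequence.
#' @return numeric output sequence of the same length.
#' @export
lti_filter <- function(block, u) {
  stopifnot(inherits(block, "lti_block"))
  as.numeric(signal::filter(block$b, block$a, as.numeric(u)))
}

#' Step response of a discrete LTI block
#'
#' @param block an `lti_block`.
#' @param t_end end time in seconds.
#' @param amplitude step amplitude.
#' @return data.frame with columns `t` and `y`, sampled at `Ts` from 0.
#' @export
lti_step_response <- function(block, t_end, amplitude = 1) {
  n <- floor(t_end / block$Ts) + 1L
  data.frame(t = (seq_len(n) - 1) * block$Ts,
             y = lti_filter(block, rep(amplitude, n)))
}
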