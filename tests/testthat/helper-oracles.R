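# Independent oracles for the dynamic blocks.
#
# step_response_pf: closed-form step response by partial fractions
# (distinct poles only) -- used for C_WB and the reduced halteres loop.
# ss_step_response: numerical ODE integration of the controllable
# canonical state-space form via deSolve -- handles repeated integrator
# poles (the passive pitch block).  Both are independent of the package's
# Tustin discretization path.

horner <- function(coefs, x) {
  # coefs descending; x may be complex
  out <- 0 + 0i
  for (cf in coefs) out <- out * x + cf
  out
}

step_response_pf <- function(num, den, t, amplitude = 1) {
  # Y(s) = amplitude * num(s) / (s * den(s)); all poles must be distinct
  q <- stats::convolve(den, rev(c(1, 0)), type = "open")   # s * den(s)
  poles <- c(0 + 0i, polyroot(rev(den)))
  stopifnot(min(abs(outer(poles, poles, "-")[lower.tri(diag(length(poles)))])) > 1e-8)
  dq <- q[-length(q)] * rev(seq_len(length(q) - 1))        # dq/ds, descending
  y <- rep(0 + 0i, length(t))
  for (p in poles) {
    r <- amplitude * horner(num, p) / horner(dq, p)
    y <- y + r * exp(p * t)
  }
  Re(y)
}

ss_step_response <- function(num, den, t, amplitude = 1) {
  d0 <- den[1]
  den <- den / d0
  n <- length(den) - 1
  num <- c(rep(0, n + 1 - length(num)), num) / d0
  stopifnot(abs(num[1]) < 1e-300)  # strictly proper here
  b <- num[-1]
  A <- rbind(-den[-1], cbind(diag(n - 1), 0))
  B <- c(1, rep(0, n - 1))
  rhs <- function(tt, x, parms) list(A %*% x + B * amplitude)
  sol <- deSolve::ode(y = rep(0, n), times = t, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  as.numeric(sol[, -1, drop = FALSE] %*% b)
}

expect_traj_invariants <- function(traj) {
  s <- traj$states
  expect_true(all(diff(s$t) > 0))
  expect_equal(diff(s$t), rep(traj$config$Ts, nrow(s) - 1), tolerance = 1e-9)
  expect_true(all(s$F_mag >= 0))
  expect_equal(s$L^2 + s$T^2, s$F_mag^2, tolerance = 1e-9)
}
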