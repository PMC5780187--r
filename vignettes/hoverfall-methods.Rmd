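---
title: "Closed-loop optic-flow control of free-fall recovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optic-flow control of free-fall recovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoverfall)
```

## The problem

A hoverfly released in darkness-free fall inside a 0.40 m striped box has
roughly 200 ms to start beating its wings, right its body and redirect its
wing force upward before it hits the floor.  Behavioural evidence suggests
flies do this without any graviceptive sense of "down": the candidate cues
are the translational optic flow (OF) swept across the eye by the fall and
the body rotation rate sensed by the halteres.  `hoverfall` implements a
lumped-parameter, planar flight model built on exactly those two cues,
simulates randomized free-fall ensembles, and re-implements the
data-processing computations (trajectory differentiation, body-axis
reconstruction, stereo metrology) and the likelihood-grid identification
of the visual controller gains that a high-speed-camera study of this
behaviour requires.  Because no recordings are distributed, a synthetic
cohort generator stands in for the experimental data with the same
statistical structure.

## The model

All forces are mass-normalized (units of m/s^2), motion is planar (x
horizontal along the corridor, z vertical, floor at z = 0, release at
0.40 m) and pitch is 0 when horizontal, negative head-down.  The sample
period is the camera frame interval, Ts = 1/1600 s.

**Passive phase** (release to wingbeat onset, a random 75-150 ms): the
body falls ballistically while a pin-induced passive torque pitches it
nose-down.  The pitch follows the fifth-order transfer function

    T_passive(s) = (0.001 s^2 + 30 s) / (s^2 (0.0011 s^3 + 0.0005 s^2 + 0.01 s + 1))

driven by a step of amplitude -pi/2 (scaled by g/9.81 so a weightless
variant produces no torque).  The cubic factor has a pair of unstable
roots (+4.53 +/- 8.65i), so this block is a valid description only on the
short pre-wingbeat window it was fitted to; the package never evaluates it
beyond onset.

**Flight phase.**  At onset the wing force magnitude follows the step
response of a second-order filter with a zero,

    C_WB(s) = (0.24 s + 1.8955) / (0.01 s^2 + 0.1 s + 1),

to a gravity-sized step: it rises within ~50 ms, peaks near 25.8 m/s^2 at
0.22 s and settles at 1.8955 g.  The force stays orthogonal to the body
axis, so lift and thrust are L = cos(theta_p)|F|, T = -sin(theta_p)|F|:
like a helicopter, the fly commands forward speed by pitching.

The translational OF is the speed divided by the 0.20 m wall distance,
directed opposite to motion.  Two sign conventions coexist and are worth
being explicit about, because the literature mixes them freely:

* *reported* components (`omega_x`, `omega_z` in every output table) use
  the flow-opposite convention -- `omega_z > 0` while falling, and steady
  forward flight at the setpoint shows `omega_x = -0.04`;
* the *controllers* consume the velocity-projection convention
  (`omega_mag * cos/sin(theta_V_Rfly)`, positive moving forward/up), and
  the visual PD error is measurement minus setpoint.  This is the unique
  sign arrangement that makes the linearized loop stable and drives the
  forward-OF magnitude to the +0.04 reference; the steady state then
  shows the +0.04 reference on the projection scale and -0.04 on the
  flow-opposite scale -- the two values differ only by convention.

The OF setpoint itself (0.04) is treated as a dimensionless constant on
the internal V/d_wall scale; its conventionally quoted unit is not dimensionally
consistent with an angular rate and the model only ever compares it with
the internal OF signal.

**Control loops.**  The pitch rate is the actuated variable.  A visual PD
controller with filtered derivative, `PD_V(s) = KpV + KdV s/(tau_d s+1)`,
turns the forward-OF error into a pitch-rate command; an inner "halteres"
loop -- PI controller (KpH = 7, KiH = 0.3) cascaded with a 2 ms wing-pitch
actuator lag under unity rate feedback -- tracks that command.  Pitch is
the integral of the achieved rate, and the kinematics (semi-implicit Euler
at Ts) close the loop through the OF geometry.  This *basic* model has
three integrators between measured OF and pitch; it reproduces the first
~200 ms of recovery and then destabilizes structurally: ensemble medians
put the instability onset near 0.37-0.39 s from release, with pitch
crossing pi/2 regardless of the visual gains.

The *improved* model adds two loops (both summing into the existing
junctions): a PI force loop (Kp_wz, Ki_wz) on the vertical OF whose
integral action cancels `omega_z` while holding a non-zero steady lift --
altitude hold -- with the total force clamped at zero from below (flapping
cannot pull the fly downward along its body axis); and a PD loop
(Kp_theta, Kd_theta) on the absolute pitch, standing for a
dorsal-light-response-like attitude reference.  With the default gains the
model settles its pitch within a few ms of its final value per onset
group, never crashes over 3 s horizons, and parks at `vz = 0`,
`omega_z = 0`, `omega_x = -0.04`.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `d_wall` | 0.20 | m | corridor half-width |
| `box_height` | 0.40 | m | release height |
| `Ts` | 1/1600 | s | camera frame interval |
| `onset_window` | [0.075, 0.150] | s | wingbeat-initiation range |
| `KpH`, `KiH` | 7, 0.3 | -- | halteres PI, fixed from prior work |
| `KpV`, `KdV` | 5, 0.5 | -- | visual PD; the quantities [mle_grid()] estimates. Defaults sit on the estimation grid and give a well-conditioned recovery benchmark |
| `tau_d` | 0.01 | s | derivative filter; no canonical value exists. Slow enough to tame 1600 Hz noise, fast against the loop dynamics; configurable |
| `omega_x_setpoint` | 0.04 | internal OF units | forward-OF reference |
| `Kp_theta`, `Kd_theta` | 20, 1 | -- | absolute-pitch PD (improved) |
| `Kp_wz`, `Ki_wz` | 8, 40 | -- | vertical-OF PI (improved) |

The four improved-model gains have no canonical values; they were set once, by a
coarse grid scan against the two stated performance conditions -- mean
pitch settling within 150 ms per onset group and zero crashes over 3 s --
and are exposed in `controller_gains()`.  The scan favoured a strong
proportional vertical-OF term (`Kp_wz = 8`): it is what suppresses the
heave overshoot after the initial force transient, which otherwise swings
the OF geometry hard enough to throw the pitch loop into a large
excursion around 0.3 s.

## Numerical choices

* **Discretization.**  Every transfer function is discretized by the
  bilinear (Tustin) transform at Ts, applied directly to the polynomial
  coefficients.  Tustin preserves DC gains and stability at any step.  A
  discrete step applied at sample 0 is seen by the trapezoid rule as
  rising across the preceding half sample; tests therefore compare
  discrete outputs against continuous oracles evaluated at t + Ts/2, at
  which alignment all blocks agree with closed-form/ODE references to
  better than 1e-3 on their working windows.
* **Halteres loop reduction.**  The inner loop is linear, so it is
  simulated as its exactly reduced closed-loop transfer function
  `(KpH s + KiH)/(lag s^2 + (1+KpH) s + KiH)` rather than as a per-sample
  loop: a one-sample feedback delay would be unstable here, because the
  loop crossover (~3500 rad/s) sits at the Nyquist edge of 1600 Hz
  sampling.  The reduced loop has a near pole-zero-cancelled slow mode
  (pole -0.0375, zero -0.0429): rate commands are tracked at gain ~0.875
  within milliseconds, and the residual ~12% offset decays with a ~27 s
  time constant.  The DC gain is exactly 1, but on behavioural timescales
  the loop is a 0.875-gain follower -- a property of the published gains,
  not of the implementation.
* **Onset initial conditions.**  The passive pitch rate at onset is
  carried into the flight phase as a zero-input exponential decay of the
  2 ms actuator lag superposed on the loop response.  (Seeding the reduced
  filter's internal state directly would load the near-cancelled slow
  mode and bias the entire flight.)
* **Integration.**  Semi-implicit Euler (velocities first) at Ts;
  ballistic closed forms are reproduced to O(Ts).  Onset times are
  rounded to the sample grid.
* **Divergence guard.**  Simulations halt and flag `diverged` when
  |pitch| > pi or speed > 50 m/s, keeping ensembles finite; crash
  detection truncates at the first z <= 0 sample unless asked not to.
* **Degenerate geometry.**  Zero velocity yields zero OF with a zero
  reference angle; body-axis clouds that are degenerate in the XY
  projection fall back to a PCA axis and are flagged.

## Identification of the visual gains

The identification procedure is a per-fall maximum-likelihood map over
KpV in [0, 20] x KdV in [0, 2], averaged across falls.  The likelihood
objective is not published; the package adopts iid Gaussian residuals on
the pitch series over the 200 ms following onset (pitch is the primary
matched signal), with sd 0.08 rad -- the documented +/-5 degree pitch
measurement error.  The default grid is 41 x 41 (ranges are published,
steps are not), ties break toward the lowest-complexity controller
(smaller KdV, then smaller KpV), and candidate simulations that diverge
inside the window score -Inf.  Whether position should enter the
likelihood alongside pitch is genuinely open; pitch-only is the default
and the observed-series interface accepts any scalar series.

On synthetic cohorts this procedure is a proper parameter-recovery
benchmark *for the variant being fitted*: fitting the basic model to
basic-model cohorts at default noise recovers the generating (5, 0.5)
within one grid cell (exactly, at 44 trials, across seeds).  Fitting the
basic model to improved-model cohorts -- the analogue of fitting the
published model to real flies -- instead selects the gain pair whose
basic-model transient best mimics the stiffer improved-model pitch
response; it lands at high KpV (~17) with KdV 0.5, and the downstream
instability-onset statistic is insensitive to this choice (the 0.33-0.40 s
divergence window barely moves across the whole grid).  KpV is only
weakly identified in the improved model because the absolute-pitch loop
dominates the pitch trace.

## The synthetic cohort generator

`generate_cohort()` emulates what the tracking pipeline would hand the
analysis: per trial it draws a wingbeat onset (truncated lognormal with
implied mean 103 ms by default -- log-sd 0.28, support clipped to
[60, 180] ms, location solved numerically so the *truncated* mean is
exactly the target -- or uniform on [75, 150] ms), runs the flight
simulator, adds a small constant lateral drift for 3-D realism, and
synthesizes head/centroid/tail landmarks half a body length (uniform
10-15 mm) from the centroid along an axis tilted by per-frame Gaussian
pitch noise (sd 0.08 rad), with 0.5 mm Gaussian position noise on every
landmark coordinate.  A configurable fraction of trials is made
non-recovering, alternately by delaying the onset past the 150 ms
selection threshold and by zeroing the wing force, so both clauses of the
trial-selection filter (`select_trials()`: onset < 150 ms AND positive
climb within 300 ms) are exercised; 13 such trials in a 57-trial cohort
reproduce the 44-of-57 selection count.  A truth sidecar records
everything needed to recompute each label independently.

What the generator does *not* emulate: segmentation failures when the fly
faces the camera, yaw/roll excursions, air drag, wingbeat-resolved force
ripple, and any correlation structure in the measurement noise.  Passing
tests therefore certify the pipeline's internal consistency and its
statistical behaviour under the stated noise model -- not performance on
real footage.  Note that single-frame three-point landmarks leave the
position noise's ~0.05 rad angular contribution unaveraged (recovery
error sd ~0.10 rad); the 51-threshold point clouds of the real pipeline,
emulated in the tests, average it back down to ~0.08.

## Problem sizes

Default analyses use ensembles of 30-40 falls over 3 s horizons,
57-trial cohorts, and the full 41 x 41 estimation grid; the acceptance
script (`scripts/acceptance.R`) runs the whole pipeline -- both ensembles,
cohort generation, landmark-based pitch reconstruction and the grid fit --
in about two minutes on one core.  Unit tests use smaller grids and
cohorts chosen to keep each property sharply testable.

## Known limitations

* Planar dynamics only; yaw and roll are frozen by construction, and the
  corridor is infinite with a constant wall distance.
* The passive-pitch block is non-physical outside [0, ~0.15] s.
* The stereo quantization-uncertainty formula is implemented literally
  (delta_d / sqrt(12), giving 0.74-1.35 mm over the box depth); the
  0.46-0.62 mm range sometimes quoted for this rig is not reproducible
  from that formula and these delta_d values, and the discrepancy is
  surfaced rather than resolved.
* The "highly unstable" notion is operationalized (first |pitch| > pi/2,
  or forward-OF error exceeding 10x its value at onset) because the
  behavioural definition is visual; both thresholds are configurable.
* The improved-model gains are this package's own calibration to the two
  stated performance conditions, not independently documented values.
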