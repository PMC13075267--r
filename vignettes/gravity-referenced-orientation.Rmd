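---
title: "Gravity-referenced limb orientation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gravity-referenced limb orientation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(babyimu)
```

This vignette documents the science and the engineering decisions behind
`babyimu`: the orientation model and its conventions, the preprocessing and
fusion parameters, what the synthetic-data generator does and does not
emulate, the statistical models, and the numerical corner cases.  It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Orientation model and conventions

A tri-axial accelerometer at rest measures the surface-normal reaction to
gravity: `(0, 0, +9.81)` m/s² when flat, and generally the world vertical
rotated into the sensor frame.  We describe sensor orientation by a unit
quaternion `q` (scalar-first, sensor-to-world) and by intrinsic z-y-x Euler
angles: yaw about the world vertical, then pitch about the intermediate
y-axis, then roll about the sensor x-axis.  This convention is chosen so
that on static data the angles reduce exactly to the gravity-vector
formulas

$$\text{pitch} = \arctan\!\frac{-X}{\sqrt{Y^2+Z^2}}, \qquad
  \text{roll} = \operatorname{arctan2}(Y, Z),$$

with `(X, Y, Z)` the sensor-frame gravity components.  Two consequences are
worth making explicit:

* **Sign of pitch.** A rotation that moves `+9.81 sin 45°` onto the x-axis
  has pitch −45° under this formula; its magnitude is 45°.  The sign
  convention follows the formula, not the colloquial description of the
  rotation.
* **Quadrant-aware roll.** We use `arctan2(Y, Z)` rather than the scalar
  `arctan(Y/Z)`, so inverted postures (`|roll| > 90°`) are representable.
  The two agree everywhere in (−90°, 90°); this is a deliberate extension,
  because infant limbs do invert.

Yaw is *unobservable* from the accelerometer alone: any rotation about the
world vertical leaves the gravity vector unchanged.  `accel_only_orientation()`
therefore pins yaw to exactly 0 and marks the series yaw-unobservable;
downstream code refuses to compute yaw-dependent quantities (full-3D angular
velocity, yaw circular SD, generalized variance) from it.

## 2. Preprocessing

**Gravity isolation.** `lowpass_gravity()` applies an order-4 Butterworth
low-pass forward and backward (zero phase, unit DC gain).  The default
cutoff is 8 Hz: infant-generated movement acceleration is mostly below that
band edge, and zero-phase filtering avoids the group delay that a causal
filter would inject into orientation timing.  Note that 8 Hz sits close to
the 10 Hz Nyquist frequency at the 20 Hz sampling rate, so the transition
band is narrow and the filter removes only the topmost band; the fusion
filter's accelerometer gating (below) handles what passes through.  The
implementation matches the standard forward–backward scheme with
odd-reflection edge padding and steady-state initial conditions, so a
constant input is reproduced exactly from the first sample.

**Gyroscope bias.** MEMS gyroscopes carry a quasi-constant zero-rate offset;
integrated, 0.02 deg/s becomes 6° of drift over a 5-minute window.
`estimate_gyro_bias()` detects quiescent runs — gyro magnitude below
3 deg/s sustained for at least 2 s — and tracks the bias with a per-sample
exponential moving average (coefficient 0.02) over those runs.  The
thresholds are our choices (the estimator design names the strategy, not the
numbers) and are exposed as arguments: 3 deg/s is far above the gyro noise
floor yet far below genuine limb rotation; 2 s excludes momentary pauses
inside movement bouts; EMA 0.02 averages roughly the last 50 quiescent
samples, which converges exactly on static data while staying responsive.
With no quiescence found the estimator returns zero bias with a warning
rather than guessing.

## 3. Sensor fusion

`fuse_orientation()` is a gradient-descent accelerometer/gyroscope/
magnetometer fusion filter in the Madgwick family.  Each step:

1. propagates the quaternion with the gyroscope using the exact quaternion
   exponential (at 20 Hz and vigorous movement, first-order integration
   measurably underperforms);
2. evaluates the alignment error between the predicted and measured gravity
   and magnetic-field directions **at the propagated state** (the
   measurement belongs to the post-step instant; evaluating at the previous
   state introduces a one-sample lead that grows with rotation rate at low
   sampling rates);
3. descends the error gradient with authority `beta` (default 0.1 rad/s).
   The gradient is normalized, but with a *saturated* normalization: below a
   small gradient magnitude the step becomes proportional to the error.  A
   strictly fixed-size step limit-cycles ("chatters") around the exact
   solution on clean data; the saturation removes the cycle while leaving
   behavior at substantial error identical to the classical filter.
4. skips the correction entirely when the measured accelerometer magnitude
   deviates from 9.81 m/s² by more than 0.5 m/s² — during such samples the
   accelerometer measures movement, not gravity direction.  This validity
   gate is standard inertial-fusion practice.

The earth magnetic-field reference is rebuilt from the current measurement
each step (horizontal magnitude + vertical component), so only the field's
dip angle matters, declination is irrelevant, and yaw is a *relative*
heading — sufficient because the analyses compare orientation within a
recording, never against geographic north.

Initialization uses the first sample (tilt from the accelerometer, heading
from the tilt-compensated magnetometer); the first `warmup_s = 5` seconds
are flagged and excluded from metrics.  Samples within 0.1° of the gimbal
poles (`|pitch| = 90°`) are flagged; `window_metrics()` interpolates their
yaw/roll circularly from neighbors, since the two are not separately
identifiable there.

## 4. Composite angular velocity

Two modes:

* **Full-3D** (`angular_velocity_full()`): the geodesic angle between
  consecutive quaternions times the sampling rate,
  `2·arccos(|⟨q_i, q_{i+1}⟩|)·(180/π)·fs`.  This is the standard composite
  of all three angle rates; it reduces exactly to the plain rate on
  single-axis motion, and on simultaneous pitch+roll motion it equals
  `sqrt(dpitch² + droll²)·fs` up to discretization.  Alternative composites
  (e.g., root-sum-square of the three Euler rates) differ only at large
  simultaneous excursions; the geodesic rate is the default because it is
  parameterization-free.
* **Accelerometer-only** (`angular_velocity_accel_only()`): the
  root-sum-square of the wrapped pitch and roll finite-difference rates.
  Yaw motion is invisible by construction, and differentiation amplifies
  whatever noise and movement-acceleration contamination the pitch/roll
  series carry, so this mode is a coarse estimate — useful when the
  hardware has no gyroscope, and quantified against the full-3D mode by
  `compare_angular_velocity()` (Pearson r and mean absolute difference).

Forward differences at the native 20 Hz are used without additional
smoothing: the gravity series is already band-limited at 8 Hz, and further
smoothing would bias the variability metrics downward.

## 5. Circular statistics

Pitch, roll and yaw are circular variables, so dispersion uses the mean
resultant length `R̄`: the circular SD is `sqrt(−2 ln R̄)` (exactly the
generating σ for a wrapped normal; equal to the linear SD to within ~σ² for
tight data).  Multi-axis variability uses the circular covariance matrix
with sine deviations about the circular means,

$$\Sigma_{jk} = \frac1n \sum_i \sin(\theta_{ij}-\mu_j)\,\sin(\theta_{ik}-\mu_k),$$

in radians, and the **generalized variance** is its determinant.  The
sine-deviation form is the standard circular-statistics construction; a
`linearized` option (ordinary covariance of wrapped deviations) is provided
behind a switch, and the two agree in the small-dispersion limit, which the
tests verify.  Values are reported as: circular SDs in degrees, generalized
variance dimensionless (rad⁶ scale).  Note the sine transform saturates for
large dispersions, so generalized variances from wide orientation
repertoires compress toward the top of their range.

Numerical conventions: `R̄ < 1e−12` means the circular mean (hence SD) is
undefined — metrics become `NA` rather than 0, so degenerate windows cannot
bias cohort models toward stillness; determinants in `[−1e−12, 0)` are
round-off and clamp to 0; asymmetry beyond 1e−9 is rejected as an input
error.

## 6. The synthetic-data generator

`simulate_trajectory()` emulates the study conditions: 5-minute (300 s)
segments at 20 Hz of an ankle sensor on a non-walking infant.  Movement
bouts start as a Poisson process (4/min) and last 5 s; within bouts each
Euler angle relaxes (rate 3 /s, slew-limited at 120 deg/s) toward a smooth
band-limited (0.2 Hz) Gaussian target; between bouts the limb is exactly
still.  The target amplitude is calibrated per axis so the realized
circular SD of each angle series *equals* the configured dispersion —
default (15°, 35°, 35°) for (pitch, roll, yaw), reflecting that ankle pitch
is anatomically more constrained than roll/yaw.  `render_imu()` inverts the
orientation model: accelerometer = rotated gravity + band-limited (≤ 6 Hz)
movement acceleration during bouts (SD 1 m/s²) + white noise (SD
0.1 m/s²); gyroscope = exact body rates + constant bias (≈ 0.02 deg/s per
axis, the 6°-per-5-minutes drift scale) + white noise (SD 0.2 deg/s);
magnetometer = rotated unit reference field (dip 60°, mid-latitude) + white
noise (SD 0.01).  The noise SDs are deliberately conservative for
research-grade hardware — they bound the sensor noise floor plus
attachment/strap disturbance — and the movement band sits below the 8 Hz
gravity cutoff by construction (configurable, to stress-test the filter).

The rendered gyroscope sample at `t_i` carries the mean body rate over the
preceding sample interval, the quantity an integrating rate gyro reports;
stepwise exponential integration of noise-free rendered data therefore
reproduces the true quaternions exactly, which the tests exploit as an
oracle.

**What the generator does not emulate:** biomechanical limb linkage (angles
are independent processes, not coupled joint kinematics), contact/impact
spikes, magnetic disturbance from the environment, sensor saturation, and
temperature-dependent bias drift.  Passing tests therefore demonstrate
correctness of the *algorithms* under the stated signal model, not hardware
validation on real infants.

`simulate_cohort()` generates the longitudinal study: two cohorts (default
31 increased-likelihood and 17 low-likelihood children, the 9-month visit
sizes), visits at 3, 6, 9, 12 months, and for each metric a linear model
`baseline + slope·(age−3) + child intercept + visit noise`.  Defaults place
the 3-month baselines at (14.8°, 21.4°, 24.3°, 0.025) and the monthly
slopes at (0.71, 3.63, 4.17, 0.06) for (pitch SD, roll SD, yaw SD,
generalized variance) — the scales a longitudinal infant cohort exhibits.
Noise scales are (between-child, residual) = (3, 4.5)° pitch, (5, 8)° roll
and yaw; for the generalized variance they are (0.004, 0.008), small enough
that truncation at zero (the metric's support) is rare (<1%) and does not
bias slope recovery — a Gaussian model with the visit-level spread real
determinant metrics show would be mostly negative at the 3-month mean,
which only a skewed model could represent faithfully (a known
simplification).  The gross-motor raw score is `3 + 1.7·age` plus
`msel_link` (default 1.5) points per SD of the visit's generalized-variance
deviation plus noise (SD 2.5) — a monotone link yielding a concurrent
rank correlation near 0.5 at the default strength, and an independent score
at `msel_link = 0`.  All simulated infants are non-walking.

## 7. Statistical models

`fit_age_lmm()` fits `metric ~ cohort * age_c + (1 | child)` by REML
(`lme4`/`lmerTest`).  Design choices:

* **Random intercepts only.** Repeated visits per child demand a child
  effect; random intercepts are the minimal faithful structure, and slopes
  can be added by extending the formula if a dataset warrants it.
* **Centered age.** `age_c = age − mean(age)` leaves the slope and
  interaction untouched but makes the cohort main effect the level
  difference at the average study age — the quantity of scientific
  interest — rather than an extrapolation to age 0.
* **Wald p-values by default**, Satterthwaite as an option, with the method
  recorded in the output.  At the study's sizes the Wald normal
  approximation is adequate (the acceptance suite verifies 5% ± 2% type-I
  error at less than a third of the study's children); Satterthwaite is
  there for small-sample use.
* **Singular fits** (boundary random-effect variance) are flagged and
  refit without the interaction.
* α = 0.05, no multiple-testing correction; missing metrics are dropped
  listwise per model.

`fit_angle_contrast_lmm()` stacks the three circular SDs long and fits
`csd ~ angle * age_c + (1 | child)` with pitch as reference: the `angle`
terms are average level differences over the study ages and the
interactions are per-month slope differences.

`correlate_msel()` pairs a child's metric at one age with their gross-motor
score at the same or a later age (predicting the past is disallowed),
restricted to non-walking infants so that global body posture is comparable
across time points, and reports Spearman correlation (average ranks for
ties; Pearson available).

## 8. Problem sizes and runtimes

The test suite and acceptance script use: 5-minute, 20 Hz segments (6000
samples) for pipeline checks; 10 seed-fixed rendered recordings for
orientation recovery; n = 10⁴ draws for the circular-SD oracle; 100
simulated cohorts of 50 children × 4 visits for slope-recovery coverage;
1000 reduced-size (12-children) null cohorts for type-I calibration; and
1000 null cohorts at the 9-month visit size (48 children) for the
rank-correlation calibration.  These sizes give stable Monte-Carlo
estimates (binomial SE ≤ 0.7% at 1000 replicates) while the whole suite
runs in a few minutes on one core.

## 9. Known limitations

* Yaw is relative heading; absolute geographic orientation is out of scope.
* The generalized variance saturates for very wide orientation
  repertoires (sine-deviation compression).
* The accelerometer-only mode under-estimates rotation with any yaw
  content and amplifies noise by differentiation; it is a fallback, not a
  substitute for fusion.
* The cohort generator's Gaussian visit noise cannot reproduce the skewness
  that bounded, determinant-based metrics show in real data; slope recovery
  is unaffected, distributional tails are not faithful.
* Estimation is offline (whole-recording); no streaming interface.
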