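# babyimu

Gravity-referenced estimation of infant limb orientation from ankle-worn
inertial sensors, and longitudinal analysis of orientation variability.

## The problem

Wearable-sensor studies of infant movement usually quantify *linear*
kinematics from movement-generated acceleration and discard the gravitational
component of the accelerometer signal as background.  But gravity dominates
the accelerometer reading, and its direction in the sensor frame encodes limb
*tilt* stably — postural information (orientation repertoire, postural
transitions) that linear metrics miss and that is clinically relevant to
early neuromotor development.  `babyimu` implements the complementary,
gravity-referenced view for tri-axial accelerometer + gyroscope +
magnetometer recordings sampled at low rates (the supported study design is
20 Hz, 5-minute free-movement segments at 3, 6, 9 and 12 months of age).

## What it computes

With the sensor-frame gravity vector `(X, Y, Z)` (isolated by a zero-phase
8 Hz low-pass Butterworth filter), tilt follows from

    pitch = arctan( -X / sqrt(Y² + Z²) ),      roll = arctan2( Y, Z )

Yaw — rotation about the world vertical — leaves gravity unchanged and needs
gyroscope + magnetometer fusion: a Madgwick-style gradient-descent filter
propagates a unit quaternion with the (bias-corrected) gyroscope and corrects
it toward the measured gravity and magnetic-field directions.  Constant
gyroscope bias is estimated from quiescent periods with an
exponential-moving-average tracker (an offset of 0.02 deg/s would otherwise
drift 6° over a 5-minute window).

From the angle series the package derives:

* **Composite angular velocity** — the geodesic rotation rate between
  consecutive quaternions (full-3D mode), or `sqrt(Δpitch² + Δroll²)·fs`
  when only an accelerometer is available (coarse, yaw-blind mode), plus the
  correlation/MAD comparison between the two.
* **Orientation variability** — per-axis circular standard deviations
  `sqrt(-2 ln R̄)` and the *generalized variance*, the determinant of the
  circular (sine-deviation) covariance matrix of pitch, roll and yaw over a
  window.
* **Longitudinal models** — linear mixed-effects models of each metric with
  cohort, linear age, their interaction and a random intercept per child;
  an angle-contrast model for level/slope differences between roll, yaw and
  pitch; and Spearman correlations between the generalized variance and
  concurrent or future gross-motor raw scores in non-walking infants.

A synthetic-data module generates ground-truth orientation trajectories
(quiescence alternating with Poisson movement bouts), renders raw IMU streams
from them (rotated gravity + movement acceleration + noise; biased noisy
gyro; rotated magnetic field), and simulates longitudinal cohorts — so every
stage is testable against known truth without access to recorded infant
data.

## Worked example

```r
library(babyimu)

truth <- simulate_trajectory(duration = 300, fs = 20, seed = 7)  # ground truth
rec   <- render_imu(truth)                                       # raw sensor streams

bias   <- estimate_gyro_bias(rec)
orient <- fuse_orientation(correct_gyro(rec, bias))
window_metrics(orient)
```

```
<gyro_bias> (-0.05201, -0.01015, -0.00316) deg/s from 3250 quiescent samples
<orientation_series> 6000 samples @ 20 Hz, mode fused
  flagged: 100 warmup, 0 gimbal, 0 invalid
<variability_metrics> window [0, 300] s, n = 5900
  circular SD (deg): pitch 15.10, roll 35.22, yaw 35.20
  generalized variance: 0.003281
```

The recovered circular SDs sit on the generator's targets (15°, 35°, 35°);
the first 5 s are flagged as filter warm-up and excluded.  The bias estimate
reflects the injected constant offset plus gyro noise averaged over the
detected quiescent samples.

```r
full <- angular_velocity_full(orient)
ao   <- angular_velocity_accel_only(accel_only_orientation(lowpass_gravity(rec)))
compare_angular_velocity(full, ao)
#> r = 0.59, MAD = 46.89 deg/s
```

The accelerometer-only mode is deliberately coarse: movement-generated
acceleration (and measurement noise) contaminates the gravity direction
during bouts and is then amplified by differentiation, which is precisely
why the fused mode is preferred when a gyroscope is available.

```r
tab <- simulate_cohort(synth_cohort_config(seed = 7))
fit_age_lmm(tab, "roll_csd")
```

```
<lmm_result> 192 obs, 48 children; p-values: wald
            term estimate    se df        p
     (Intercept)  36.2700 1.840 NA 8.65e-87
       cohortILA   0.3631 2.290 NA 8.74e-01
           age_c   4.0300 0.259 NA 1.59e-54
 cohortILA:age_c  -0.4468 0.322 NA 1.66e-01
```

`age_c` is the per-month slope of the roll circular SD (the generator
injected 3.63 °/month; the estimate is within two standard errors), and the
null cohort terms reflect that both simulated cohorts were generated
identically.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "babyimu.R", package = "babyimu"))')
Rscript $CLI simulate --duration 300 --seed 7 rec.csv
Rscript $CLI orient --mode fused rec.csv orient.csv
Rscript $CLI metrics orient.csv metrics.json
```

Recordings are CSV (`time_s, acc_{x,y,z} [m/s²], gyr_{x,y,z} [deg/s],
mag_{x,y,z}`) with metadata in a sidecar JSON; other column layouts/units are
declared via `imu_dialect()`.

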