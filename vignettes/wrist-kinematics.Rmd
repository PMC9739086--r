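---
title: "Wrist kinematics from a 9-DoF IMU: model, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrist kinematics from a 9-DoF IMU: model, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristkin)
```

wristkin reconstructs the earth-frame trajectory and instantaneous speed of
a wrist-worn inertial sensor over a short capture — the processing a
sports-biofeedback wearable performs on board between "capture finished"
and "results on the phone". This vignette is the package's account of that
science: the model and its assumptions, the parameters that matter, what
the synthetic generator does and does not emulate, and the numerical
choices behind the implementation.

## The estimation problem

A capture is a fixed-rate record of a 9-DoF IMU: specific force (3-axis
accelerometer, m/s²), angular rate (3-axis gyroscope, rad/s), and magnetic
field (3-axis magnetometer, gauss), in body axes following the
north-east-down (NED) convention. The default capture regime is 3000
samples at a 0.002 s period — 6 s, enough for one complete throwing
movement. From this the pipeline estimates, per sample:

* the orientation quaternion of the device relative to the earth frame;
* earth-frame dynamic acceleration (specific force rotated to earth axes,
  gravity removed);
* velocity and position by time integration;
* scalar speed, the per-sample Euclidean norm of velocity.

Orientation is carried exclusively by unit quaternions
$(q_0, q_1, q_2, q_3)$ (Hamilton convention, scalar first). Euler angles
exist in the package only for the human-readable stabilization plot,
because the yaw/pitch/roll decomposition loses a degree of freedom when
the pitch axis aligns with the yaw axis (gimbal lock); `quat_to_euler()`
flags those samples instead of guessing.

### Frame convention

One convention is used package-wide and is worth stating precisely, since
quaternion sign errors are the classic failure mode of this kind of
pipeline. The rotation matrix $R(q)$ produced by
`quat_to_rotation_matrix()` is taken as the **earth-to-body** map: the
synthetic generator manufactures body-frame readings as
$R(q)\,(a_e - g)$, the fusion filter's measurement model predicts
body-frame reference directions as $R(q)\,\hat d$, and
`rotate_body_to_earth()` applies the inverse (transpose) of $R(q)$ to
bring accelerations back to earth axes. Gravity is $(0, 0, +g)$ along
earth Down, so a stationary, level accelerometer reads the reaction
$(0, 0, -g)$. Because generator, filter, and kinematics all share the one
convention, the chain closes: the loop-closure test requires the
reconstructed earth-frame dynamic acceleration of a noise-free throw to
match the generator's ground truth within 2% relative RMS.

## Orientation fusion

The fusion filter is the gradient-descent design widely used on
microcontrollers. Each step integrates the gyroscope through the
quaternion kinematics and corrects along the negative gradient of a
geometric objective:

$$\dot q = \tfrac12\, q \otimes (0, \omega) \;-\; \beta\,
\frac{\nabla f}{\lVert \nabla f \rVert},
\qquad q \leftarrow \mathrm{normalize}(q + \dot q\,\Delta t)$$

where $f(q)$ stacks the residuals between the predicted and measured
directions of gravity and of the magnetic field. The magnetic reference is
re-derived each step from the measurement rotated into earth axes, with
its east component folded into north — the standard guard against
magnetic declination entering the tilt estimate. With $\beta = 0$ the
filter is exactly gyro dead reckoning (a property pinned by test); with
consistent stationary input the estimate is a fixed point.

Parameters (`fusion_config()`):

* **`beta`** (dimensionless, default 0.1) — the corrective step in rad/s.
  It trades gyro-bias rejection against dynamic-acceleration contamination:
  during high-dynamics motion the accelerometer no longer points along
  gravity, and the correction drags the attitude toward a wrong vertical at
  up to $\beta$ rad/s. 0.1 is the order of magnitude recommended in the
  filter's own literature for consumer MEMS gyros; users processing
  noise-free or high-grade gyro data benefit from much smaller values (the
  out-and-back closure test demonstrates the effect).
* **`sample_period`** (s, default 0.002) — the capture clock. The sensors'
  internal refresh is of the same order (476 Hz for accelerometer and
  gyroscope), so the polling loop reads essentially fresh values each tick;
  the magnetometer refreshes at only 40 Hz and is treated as
  sample-and-hold, exactly as a polling loop would observe it.
* **`magnetic_reference`** — earth-field direction in NED, default a
  mid-latitude northern field with 60° dip. Only the direction matters.
* **`initial_orientation`** — identity by default. The filter starts
  wrong and is allowed to be: the **stabilization warm-up** (`stabilize()`,
  default 20 s) runs the filter on a stationary head until the estimate
  settles, declaring convergence when yaw, pitch, and roll each move less
  than 0.5° over the final second. Tests require a 30° initial error to
  converge within 1° inside the warm-up, and the per-sample Euler history
  is returned for a stabilization plot.

A persistent gyro bias (the tests use 0.5 °/s) does not destabilize the
filter; it settles to a fixed point a bounded tilt away from truth
(< 2° in the test conditions), which is the expected behaviour of this
filter class.

## The kinematics chain

`process_capture()` executes, in order: fuse → rotate to earth →
subtract gravity → smooth → integrate to velocity → high-pass → ZUPT →
speed → integrate to position. Stage failures abort with the stage name.

**Smoothing** (`smoothing_window`, default N = 50 samples = 100 ms). The
noise filter is the trailing equal-weight moving mean: take the last N
samples, sum, divide by N, recomputed at every new sample; startup samples
use the mean of what exists so far. The device literature sometimes labels
this filter an "EWMA"; the computation described and implemented is an
equal-weight (boxcar) window, and a true exponentially weighted variant is
available behind `smoothing_type = "exponential"` for users who want the
name taken literally. The measured −3 dB point of the N = 50 window at
500 Hz is ≈ 4.4 Hz (the first spectral null is at 10 Hz). A published
"approximate cutoff" of 115 Hz for this window does not follow from any
standard moving-average formula we know and is not treated as a testable
property.

**Integration** is the left-rectangle rule: exact for piecewise-constant
signals, error bounded by one rectangle of area per step on smooth ones —
at 500 Hz this is never the dominating error. Velocity starts at 0;
position starts at the origin, and the track is anchored so that the
first sample is exactly (0, 0, 0). Position is never filtered: a
high-pass on position would erase genuine displacement.

**DC removal** (`highpass_cutoff`, default 50 Hz; `highpass_order`,
default 1). Integration turns any small acceleration error into a
velocity offset or ramp, so a high-pass (single-pole Butterworth, designed
via the `signal` package) strips the drift. The 50 Hz default reproduces
the device's printed setting, but deserves a warning: human throwing
motion lives below ~5 Hz, and a 50 Hz cutoff removes nearly the whole
motion band along with the drift (running the default on a simulated
throw collapses the peak speed by more than an order of magnitude). The
package keeps the printed default for fidelity and exposes the parameter;
all reconstruction examples and the end-to-end tests use **0.1 Hz**, a
drift-removal cutoff sitting well below the motion band, which we consider
the physically sensible choice. The tension is deliberate and documented
rather than silently "fixed".

**Zero-velocity update** (`zupt_limit` ±0.3 m/s², `zupt_count` 60
samples = 120 ms). A resting IMU never reads exactly zero, so integrated
velocity creeps. Whenever all three smoothed dynamic-acceleration
components stay strictly inside the window for at least the required run
of consecutive samples, the device is declared stationary and velocity is
forced to exactly 0.0 over the entire run. The window test uses the
smoothed signal because that is the signal available at this stage of the
chain, and it zeroes all three axes together. The implementation is
run-length based and is checked sample-for-sample against a naive
run-scanning oracle on randomized inputs.

### Error budget of a reconstruction

On a noise-free simulated throw the pipeline recovers the peak hand speed
within 10% and the top-view rotation radius within 20% (both asserted in
the end-to-end tests). The residual errors have three understood sources,
visible in the out-and-back closure test:

* ZUPT truncation: the moving mean delays velocity by ~N/2 samples, and a
  zero-velocity window cuts that delayed tail, losing a few centimetres of
  displacement per stop;
* high-pass state: the filter's memory decays across rest phases, slightly
  biasing the next movement segment;
* fusion tilt at default gain: during sustained dynamics, the
  accelerometer correction misprojects gravity by up to
  $g \sin(\beta t)$ until the quiet phases re-align the estimate.

None of these grows with time inside a 6 s capture; all three grow without
bound outside one — see Limitations.

## The synthetic generator

`simulate_truth()` samples a parametric path $p(t)$, $q(t)$ on the capture
clock and differentiates by central differences (exact for linear paths,
0.1%-accurate on circular ones at 500 Hz; presets also carry analytic
velocities for tight tests). `truth_to_imu()` then inverts the front of
the pipeline: body specific force $R(q)(a_e - g)$, body angular rate
$2\,\mathrm{Im}(q^* \otimes \dot q)$, magnetometer
$R(q)\,m_{\mathrm{ref}}$ held at its 40 Hz refresh, plus seeded white
noise, constant biases, and a slowly growing gyro bias
(`noise_model()`, defaults: accelerometer σ = 0.05 m/s², gyro σ = 0.2 °/s
with 0.5 °/s bias, magnetometer σ = 0.005 gauss — plausible for this
sensor class). All randomness flows from the single seed; equal seeds give
bit-identical captures, and generation restores the caller's RNG state.

The **discus preset** (`discus_spec()`) emulates the phase structure of a
throw on a circle of radius 0.9 m (an adult arm-plus-shoulder lever):
hold, reverse half-arc wind-up, pause at the direction change, forward
turn, release segment peaking at 12 m/s (an amateur hand speed; the
constructor rejects kinematics that would exceed the gyroscope's
±2000 °/s full scale), and final rest, with a slight arm lift during
release. Angular-speed segments are $\sin^2$ bumps, so velocity is
continuously differentiable and the ground-truth speed profile has three
local maxima — wind-up, turn, release — with the global maximum at
release; setting `windup_fraction = 0` removes the first peak. Rest
phases are long enough (≥ 0.3 s) for the zero-velocity rule to engage.

What the generator does **not** emulate: sensor saturation (a real ±8 g
accelerometer clips at 78 m/s², which a hard throw's centripetal
acceleration can exceed), axis misalignment and scale-factor error beyond
the linear offset/slope model, magnetic disturbance from nearby iron,
vibration from a loosely strapped device, and any biomechanical
variability of real athletes. Passing end-to-end tests therefore show the
chain is a correct inverse of its own sensor model — not that a physical
device of this grade achieves the same accuracy on a real wrist.

## Calibration and digitization

`apply_calibration()` applies the per-axis affine correction
$(raw - offset) \times slope$ to all nine channels; parameters load from
YAML. Estimating the constants from maneuvers is out of scope — only a
convenience helper (`estimate_accel_offset()`, clearly not part of the
device's own procedure) infers accelerometer offsets from a stationary,
level segment. `counts_to_units()` converts signed digitizer counts at
$2 \cdot FS / 2^{16}$ per count: 0.244 mg at ±8 g, the one stated
resolution that equals the derived LSB (the gyroscope's and
magnetometer's stated sensitivities are datasheet values and are carried
as data only).

## Telemetry framing

The radio link carries 20 bytes per frame, so each sample packs as four
5-byte fixed-decimal ASCII fields `xx.xx` — x, y, z, speed — giving
00.00–99.99 at two decimals, no sign. Values are quantized
half-away-from-zero (deterministic across platforms, up to the usual
binary representation of decimal literals). Since positions can be
negative, `encode_track()` defaults to shifting each field by a
per-capture offset reported alongside the stream (and in a JSON sidecar
next to stream files); `mode = "strict"` rejects out-of-range values
instead. Overflow is always an error, never saturation. Encode and decode
are exact mutual inverses on two-decimal values, fuzz-tested on 10⁴
random quadruples.

## Problem sizes in the test suite

The suite runs at the capture's native scale where the science demands it
(3000-sample captures at 500 Hz, a full 20 s warm-up for the convergence
and bias tests, a 10× warm-up for the fixed-point oracle) and at reduced
scale where only the property matters (4 s streams at 250 Hz for the
independent-implementation cross-check; 10⁴ short randomized cases for
the ZUPT and codec fuzz suites). The whole suite completes in well under
a minute on one CPU.

## Limitations

Inertial dead reckoning double-integrates noise: position error grows
without bound, and no high-pass/ZUPT combination changes that asymptotic.
The chain is built for short, bounded captures that begin and end at rest;
long-duration records need an external reset (satellite positioning,
vision, anchor ranging) that is explicitly out of scope. The 5-byte frame
format caps every reported coordinate at 99.99 m and two decimals —
centimetre quantization that is invisible for a throw but real. And the
fusion gain is a compromise, not a constant of nature: the right `beta`
for a rate-table test bench is not the right `beta` for a wrist mid-throw.
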