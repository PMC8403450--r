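---
title: "Models and methods behind gaitval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gaitval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitval)
```

# What the package computes

`gaitval` implements two wearable gait-analysis pathways and the complete
statistical machinery needed to validate them against marker-based
optoelectronic capture, the criterion standard of human movement analysis:

* a **full-body kinematics pathway**: a configurable rigid-segment chain is
  scaled to the participant, driven either by marker trajectories
  (weighted least-squares inverse kinematics) or by segment-mounted IMU
  orientations (geodesic-residual inverse kinematics), gait events are
  detected from foot kinematics by four procedures plus a consensus rule,
  and per-cycle spatiotemporal parameters are derived;
* a **pocket-smartphone pathway**: accelerometer and gyroscope streams are
  synchronised by linear interpolation (spherical linear interpolation for
  orientation data), fused into a device orientation by Madgwick's
  gradient-descent filter, reduced to a global vertical acceleration, and
  mined for heel-strike/toe-off events by a peak/nadir procedure; stride
  length comes from a linear regression on stride frequency and vertical
  acceleration variance;
* an **agreement suite**: Bland–Altman bias and limits of agreement with
  95% confidence intervals, the D'Agostino–Pearson normality omnibus,
  Welch tests of a system's bias distribution against pooled reference
  difference distributions, and waveform similarity of joint-angle curves
  by the Linear Fit Method (LFM) with mean absolute error.

Because no raw laboratory recordings accompany the published validation
this package targets, a **ground-truth simulator** generates coherent
marker, IMU and phone recordings from one kinematic trajectory with known
events and parameters; every pipeline stage is validated against that
truth.

# Coordinate and signal conventions

All internal units are SI (m, s, rad, m/s^2); degrees appear only at
reporting boundaries. World and pelvis axes are x = right, y = forward,
z = up. Quaternions are scalar-first, right-handed frame rotations mapping
local (sensor/segment) coordinates to the parent/world frame. The pelvis
anatomical frame is built from the four iliac-spine markers: origin at the
ASIS midpoint, first axis along RASIS−LASIS, forward axis through the
ASIS/PSIS midpoints orthogonalised against it. "Anterior" in the event
detectors always means the pelvis forward axis; "vertical" the pelvis up
axis.

# The kinematic model

The shipped default chain (`default_model()`) is a reduced full-body
model: pelvis root; per leg a 3-DoF ball-and-socket hip (Cardan sequence
XYZ: flexion about the right axis, ab/adduction about the forward axis,
axial rotation about the vertical), a 1-DoF knee and a 1-DoF ankle; and
one 6-DoF arm (3-DoF shoulder with sequence XZY — chosen over the
standards-body recommendation for its lower gimbal-lock incidence — 1-DoF
elbow, forearm pronation and wrist flexion). These are exactly the eleven
DoF whose waveforms the validation literature reports; the chain is
configuration-driven, so richer models (head, lumbar joints) are a config
away rather than a code change. Segment lengths and marker offsets follow
standard anthropometric proportions of a 1.70 m reference stature;
`scale_model()` applies the proportional-scaling rule (every offset and
local marker position multiplied by stature ratio).

Flexion and dorsiflexion are positive by convention; per-DoF sign factors
map the clinical direction onto the raw Cardan axis rotation.

## Inverse kinematics

Both IK variants minimise a per-frame least-squares objective with a
damped Gauss–Newton (Levenberg–Marquardt) solver using numerical
Jacobians, warm-started from the previous frame (max 100 iterations, step
tolerance 1e-10; the line search never accepts an objective increase).
The marker residual is the weighted distance between observed and
model-determined marker positions (weights default to one; the published
procedure states a weighted objective without giving weights). The
orientation residual is the rotation vector of
\(q_{model}^{-1} \otimes q_{obs}\) per instrumented segment, whose norm is
the geodesic angle — the natural metric when the source material says only
that errors between experimental and model IMU frames are minimised. DoF
whose Jacobian column vanishes (unobserved segments) are flagged
unidentifiable rather than silently pinned; frames that fail to converge
carry the previous pose and are flagged.

On noise-free data generated by the package's own forward kinematics both
variants recover joint angles to better than 1e-6 rad over 11-DoF chains
(the acceptance suite runs 500 frames of each).

# Gait events

Four marker procedures are implemented behind a method enum (the cited
event-detection literature is paraphrased, not restated, in the sources
this package follows, so the operational definitions are this package's
own reading and are deliberately isolated for replacement):

* `interheel` — heel strikes at local maxima of the horizontal inter-heel
  distance, attributed to the anterior foot. During double support both
  feet are planted and the distance plateaus; plateaus report their first
  sample, which is the strike.
* `foot_com_velocity` — heel strike at local minima, toe-off at local
  maxima of the foot-centre vertical velocity.
* `coordinate` — heel strike at maxima of anterior heel position relative
  to the pelvis, toe-off at maxima of posterior toe position.
* `velocity` — sign changes of the anterior heel (toe) velocity.

The consensus combiner clusters same-kind, same-side candidates within a
0.05 s window (single linkage) and emits the cluster median when at least
two methods support it — median-of-cluster is robust to one deviant
method, which is the stated intent of combining them. Output streams are
forced to alternate heel strike / toe-off per side.

The phone detector low-passes the gravity-subtracted vertical acceleration
with a zero-phase 4th-order Butterworth at 2 Hz, finds positive peaks with
a minimum prominence (0.3 m/s^2) and separation (0.3 s), labels each peak
high or low against the median of its neighbouring peak amplitudes, and
emits the first nadir after a high peak as an ipsilateral heel strike and
after a low peak as an ipsilateral toe-off. The first 2 s are excluded as
the fusion burn-in. Events are matched across systems by greedy
nearest-time one-to-one matching within 0.15 s (about half a swing phase;
the source material states the exclusion rule but no tolerance), and
unmatched events are excluded from agreement statistics.

## Zero-phase filtering

Event times must not be lag-shifted, so all filtering is forward–backward
(the stated filter is only "4th order Butterworth low-pass at 2 Hz");
the effective magnitude response is the square of the single-pass one,
i.e. steeper than the nominal order, with exact −3 dB verified against the
analytic transfer function in the tests. Edges use odd-reflection padding
of three filter lengths plus steady-state initial conditions. There is no
`signal`-package dependency: the bilinear-transform design is implemented
here and agrees with standard scientific-library coefficients to machine
precision.

# Sensor fusion

`madgwick_step()` implements the IMU variant (accelerometer + gyroscope)
of the gradient-descent orientation filter: the quaternion rate from the
gyroscope minus `beta` times the normalised gradient of the
gravity-direction objective. The magnetometer is recorded but unused —
indoor magnetic disturbance makes yaw unreliable, and only the vertical
acceleration is consumed downstream, so yaw is only relatively defined.
Defaults: `beta = 0.1` rad/s (the method's published default; the
validation study leaves it unnamed), initial orientation from the first
accelerometer sample (tilt with zero yaw), gravity 9.80665 m/s^2. With
`beta = 0` the filter reduces exactly to gyroscope integration, which the
tests exploit as an oracle. A 2 s burn-in is excluded from event detection
to avoid convergence transients.

# Spatiotemporal parameters

Per cycle (bracketed by ipsilateral heel strikes, containing exactly one
ipsilateral toe-off): stride duration; stance (strike to ipsilateral
toe-off); swing (toe-off to next strike); double support (strike to
contralateral toe-off, when observed); cadence = 60/stride in strides per
minute, computed per cycle and summarised by the mean; stride length as
the sagittal-plane (pelvis forward axis) displacement of the foot between
the bracketing strikes; stride speed = length/duration; step width as the
coronal-plane (pelvis right axis) inter-foot distance at the strike.
Summaries report mean, sample SD (n−1) and CV = 100·SD/mean.

The phone cannot observe displacement directly; its stride length is the
linear model SL = a·f_stride + b·Var(a_vert) + c fitted by ordinary least
squares. The coefficients of the published system are not public, so the
package ships `calibrate_stride_length_model()`, which fits on a seeded
synthetic corpus; these are calibration constants of this package's
synthetic world and are never presented as published values. The
acceleration variance is computed per cycle on the unfiltered
gravity-subtracted series (a flag on the pipeline switches to the filtered
series).

The IMU pathway has no absolute positions either; forward travel is
reconstructed from the stance-foot constraint (the heel between its strike
and toe-off is world-stationary), a standard zero-velocity-update
argument. Cycles reaching into the first/last 0.25 s are dropped because
both the zero-phase filter and the travel reconstruction are unreliable at
the record edges.

# Agreement statistics

* **Bland–Altman**: differences d = test − reference; bias = mean(d); SD
  with divisor n−1; limits of agreement bias ± 1.96·SD; 95% CIs from the
  t distribution, with the LoA standard error using the classical
  √(3/n)·SD approximation.
* **D'Agostino–Pearson**: K2 = Z(skewness)² + Z(kurtosis)² against χ²(2),
  with the Johnson-SU skewness transform and the Anscombe–Glynn kurtosis
  transform; a warning is issued below the standard n ≥ 20 validity
  floor. Type-I error at nominal 5% is verified to lie in [0.04, 0.06]
  over 10,000 seeded normal samples.
* **Welch tests**: computed from summary statistics (mean, SD, n per
  group) with Welch–Satterthwaite degrees of freedom, so a measured bias
  distribution can be tested against pooled literature difference
  distributions (patients vs controls; ON vs OFF medication states) whose
  raw data are unavailable. The pooled distributions' sample size is not
  published; it is a config input (default 100) and reported with the
  result rather than guessed silently.
* **LFM**: the test waveform (101 points over the normalized gait cycle)
  regressed on the reference waveform — the criterion is the reference
  time series, fixing the regression direction — yielding amplitude
  scaling α₁, offset α₀ and R² (squared Pearson correlation), plus the
  mean absolute error in degrees. Concurrent validity bands: very high
  above R² = 0.75, fair-to-high in [0.40, 0.75], low below 0.40.

## Aggregating the published per-DoF LFM table

The package ships the published per-DoF LFM outcomes as a fixture
(`lfm_reference_table()`) and reproduces all eight of the corresponding
summary statistics with `aggregate_lfm()`. Two conventions are forced by
the numbers themselves and are worth stating loudly: the group mean of α₀
is taken over **absolute** values, and the group SDs of α₁ and |α₀| use
the **population** (divisor n) convention with LoA half-width exactly
1.96·SD — only this reading reproduces the printed means (0.699/0.671 for
α₁, 2.606/6.79 for |α₀|) and LoA (±0.685, ±4.046, ±0.346, ±8.229)
simultaneously. The printed SDs of the aggregated R² and MAE are not
reproducible from across-DoF dispersion (they are presumably
subject-level), so only their means are targeted.

```{r lfm}
tab <- lfm_reference_table()
aggregate_lfm(tab[tab$grp == "lower", ], "lower")
aggregate_lfm(tab[tab$grp == "upper", ], "upper")
```

# The synthetic world

`generate_trial()` derives every stream from one kinematic trajectory, so
cross-system comparisons have a single truth. Design choices, in the order
they matter:

* **Foot-fall first.** Ankle paths relative to the pelvis are constructed
  so each foot is exactly world-stationary during stance; hip, knee and
  ankle angles then come from closed-form two-link inverse kinematics,
  and all markers and IMU orientations from the package's own forward
  kinematics. Heel strikes land at the commanded times and stride length
  is exact by construction, which is what makes the "within one sample
  period / within 1 cm" recovery criteria meaningful rather than
  circular: the detectors and parameter code never see the construction,
  only marker positions.
* **Defaults are the targeted cohort's walking condition**: cadence
  55.2 strides/min (stride 1.087 s), stride length 0.863 m (speed
  0.794 m/s), step width 0.17 m, double-support fraction 0.1, stature
  1.70 m, 120 Hz markers/IMU, 100 Hz phone. Noise defaults: 0.5 mm marker
  noise, 0.5 m/s² accelerometer noise, 0.02 rad/s gyro noise with a
  0.01 rad/s constant bias, 0.3° IMU orientation noise — ordinary values
  for optical capture and consumer MEMS sensors.
* **The pocket signal is designed, not hoped for.** The phone detector
  presumes alternating high/low acceleration peaks whose following nadirs
  mark heel strike and toe-off. In this smooth world that structure is
  produced by two mechanisms: a pelvis vertical oscillation whose even
  (half-stride-periodic) acceleration harmonics are solved spectrally so
  that, after cancelling the thigh pendular term's even harmonics, the
  combined pocket acceleration has nadirs exactly on the heel strikes;
  and pelvic obliquity (the swing-side hip drops in late swing, amplitude
  7°) which boosts the peak preceding the ipsilateral strike and so
  provides the high/low alternation. Obliquity is real gait physiology,
  but its amplitude here is chosen for a robust alternation margin, at
  the high end of normal ranges.
* **What a green test does not establish.** The simulator has no impact
  transients, soft-tissue artifact, marker occlusion (unless `degrade()`
  is applied), turning, pathological phenomenology (freezing,
  festination) or magnetometer content. Detector performance on these
  signals bounds nothing about clinical recordings; it establishes that
  the pipeline machinery — resampling, fusion, filtering, detection,
  cycle bookkeeping, statistics — is internally correct against a known
  truth. Reproducing the published cohort-level agreement tables is
  explicitly out of reach (the raw recordings are not deposited), which
  is why the acceptance suite substitutes property-based recovery
  criteria plus the exact fixture aggregation above.
* **Known timing asymmetry.** The toe-off correlate of the phone detector
  in this world sits near mid-cycle, roughly one double-support interval
  before the commanded toe-off; phone stance/swing durations are
  correspondingly biased while stride times (strike-to-strike) are
  unbiased. The validation criteria therefore weight heel-strike-derived
  quantities.

# Numerical choices and degenerate inputs

* Slerp resolves antipodal quaternion pairs to the short arc; linear and
  spherical resampling are exact at coincident timestamps and refuse to
  extrapolate.
* Cardan extraction clamps the middle-angle sine into [−1, 1] and attaches
  a warning within 0.5° of gimbal lock.
* Peak finding treats |slope| below a tolerance as flat so that noise
  micro-wiggles cannot push a detected maximum along a plateau; plateaus
  report their first sample.
* Constant-valued DoF (e.g. a hip rotation the simulator keeps at zero)
  carry no waveform and are skipped by the LFM comparison rather than
  producing a 0/0.
* The stride-length fit refuses rank-deficient designs, naming the
  collinear feature; summaries with zero mean report CV as missing with a
  warning; Bland–Altman requires n ≥ 3 and Welch non-degenerate
  variances.
* Marker occlusion gaps are never filled silently; `fill_marker_gaps()`
  exists but must be called explicitly and only bridges short gaps.

# Limitations

Sensor-to-segment calibration is assumed known (identity in the default
config); real Xsens-to-model alignment would need a calibration routine
that is out of scope. The IMU stride length depends on the stance-foot
reconstruction and is a few centimetres biased under orientation noise —
adequate for agreement analysis, not for absolute gait speed. The phone
pathway is strictly ipsilateral: one pocket detects one side's events.
Vendor orientation streams can substitute the Madgwick estimate via a
pipeline flag, but no claim is made about which the published system used
when both existed.
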