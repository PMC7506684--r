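---
title: "Estimating cane kinematics from a shaft-mounted IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cane kinematics from a shaft-mounted IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canekin)
```

## The problem

A walking cane instrumented with a single 9-axis inertial measurement unit
(3-axis accelerometer, gyroscope and magnetometer at 100 Hz) can tell a
clinician two things about how its user walks: **when the cane actually
bears on the ground** (the ground-contact phase) and **how the shaft is
oriented in space**. Contact timing and shaft orientation together support
gait and balance assessment in users at risk of falling, and both must be
computable in real time on embedded hardware, which rules out non-causal
smoothing and large models.

`canekin` implements both estimation problems, three algorithms for each,
an evaluation layer (sample-wise accuracy, per-axis RMSE,
leave-one-subject-out cross-validation), and a fully analytic cane-gait
simulator so that every algorithm can be exercised and validated without
access to recordings.

Axis convention throughout: body x = anterior–posterior (AP),
y = mediolateral (ML), z = vertical (up); SI units (m/s², rad/s); world
gravity is $(0, 0, -9.81)$ so a static sensor measures specific force
$R^\top(0,0,+9.81)$. Orientations are unit quaternions $(w,x,y,z)$,
Hamilton convention, body-to-world; Euler angles are intrinsic Z-Y-X
(yaw–pitch–roll), in degrees.

## Ground-contact phase detection

All three detectors are causal: the label of sample $j$ uses only samples
$\le j$.

**Threshold rule.** Sample $j$ is ground contact iff
$\bigl|\,\lVert a_j\rVert - g\,\bigr| \le \tau_a$ and
$\lVert \omega_j \rVert \le \tau_\omega$, with defaults
$\tau_a = 0.2\ \mathrm{m/s^2}$, $\tau_\omega = 0.3\ \mathrm{rad/s}$
(`threshold_config()`). The rationale is that a planted cane is nearly
still. The rule is exact on ideal data and degrades quickly with vibration;
larger thresholds (around 0.7) recover part of the loss on noisy data, as
`compare_phase_methods()` on the bundled simulator reproduces.

**Gait events.** During cane gait the sagittal (ML-axis) angular velocity
carries one dominant positive peak per stride at cane mid-swing (MS),
flanked by negative troughs at take-off (end contact, EC) and landing
(initial contact, IC). `detect_events()` finds MS peaks first (prominence
default 0.5 rad/s, minimum separation 0.4 s — peaks closer than that are
merged keeping the larger), then takes the nearest preceding negative
minimum as EC and the nearest following one as IC. `events_to_phase()`
labels $[\mathrm{IC}, \mathrm{EC})$ contact and $[\mathrm{EC},
\mathrm{IC})$ no contact; samples before the first event take the label the
first event implies, and an empty event set conservatively yields all
no-contact. The method is accurate for rhythmic walking but has no concept
of non-gait activities: a carried cane produces arm-swing peaks that
generate spurious events, and stationary stretches inherit whatever label
the surrounding events imply. Because EC/IC can only be confirmed after the
MS peak, the method is also not strictly real-time; it is included as the
classical comparator.

**CNN.** A deliberately small 1D convolutional network sized for embedded
inference:

| layer | output | parameters |
|---|---|---|
| input, 20 samples × 6 channels (acc + gyro) | 20 × 6 | — |
| 1D convolution, 8 filters, kernel 3, no padding, ReLU | 18 × 8 | 152 |
| max pooling, size 2 | 9 × 8 | — |
| flatten | 72 | — |
| dense, ReLU | 8 | 584 |
| dense, sigmoid | 1 | 9 |

745 trainable parameters in total. Two printed descriptions of this
architecture are mutually inconsistent in the sources this design follows:
a single output neuron with a softmax activation is degenerate (constantly
1), and "same" convolution padding would give 809 parameters. We resolve
both by arithmetic consistency with the stated parameter count: no padding,
and a single sigmoid output neuron. The decision threshold is a strict
$p > 0.5$, so a zero network (p = 0.5 everywhere) outputs no contact — the
same conservative tie policy as the force rule's strict "exceeds 1 N".
The first 19 samples of a record, for which no full window exists, are
labelled no contact (warm-up policy).

Training (`train_cnn()`): mini-batch Adam on binary cross-entropy,
defaults learning rate $10^{-3}$, batch 64, 30 epochs, Glorot
initialization, fully deterministic given a seed. Forward and backward
passes are hand-implemented, vectorized over the window batch; the test
suite checks the forward pass against a naive per-window oracle and the
gradients against numerical differentiation. Windows are raw, unnormalized
signals, as the embedded deployment would see them.

**Voting window.** `voting_smooth()` replaces label $j$ by the strict
majority of the last 25 raw labels (truncated at the record start). Any
burst shorter than 13 samples inside a long opposite-label run is removed.
The filter is causal and therefore delays every genuine phase transition by
about half its window (~120 ms at 100 Hz); it pays off when the raw
classifier flickers more than that costs, and not otherwise — see
*Limitations*.

Ground truth for training and scoring comes from a tip force sensor: a
sample is contact iff the reaction force strictly exceeds 1 N
(`label_from_force()`).

## Orientation estimation

**Acc+Mag closed form** (`accmag_orientation()`). Assuming the
accelerometer sees only gravity, tilt follows from the measured gravity
direction. We use the exact Z-Y-X inversion
$\theta = \operatorname{atan2}(-a_{AP}, \sqrt{a_{ML}^2 + a_V^2})$,
$\phi = \operatorname{atan2}(a_{ML}, a_V)$, which recovers roll and pitch
exactly for any static pose with $|\theta| < 90^\circ$; the frequently
printed variant with square-root denominators in *both* angles is not the
inverse of any single rotation sequence and is recovered by ours in the
level case. Heading comes from the magnetometer after standard tilt
compensation — rotate the measured field back by roll and pitch, then
$\psi = \operatorname{atan2}(-m_E, m_N)$ with a four-quadrant arctangent,
referenced to the horizontal component of the configured world field
(default direction $(0.4, 0, -0.9)$ normalized, a mid-latitude field with
downward dip). Noise passes straight through, and any dynamic acceleration
biases the tilt; the method is the per-sample baseline.

**Madgwick filter** (`madgwick_update()`). First-order gyro integration
plus a normalized gradient-descent step on the gravity (and, with
`use_mag = TRUE`, magnetic field) alignment objective:
$q \leftarrow q + \Delta t\,(\tfrac12 q \otimes [0,\omega] -
\beta\, \nabla f / \lVert \nabla f \rVert)$, renormalized. The gain $\beta$
(rad/s, default 0.1 — a common published value; the sources do not state
one) is the rate at which the vector-observation solution corrects the
gyro path. $\beta = 0$ is pure strapdown integration, which the test suite
verifies against an independent exact (axis-angle) integrator. The field
reference is re-projected from the current estimate each step (only its
horizontal/vertical split is constrained), so no absolute field vector is
needed. Two numerical guards: a zero-norm accelerometer sample skips the
corrective step, and a numerically-zero gradient (residual at machine
precision) is not normalized — otherwise roundoff would be amplified into a
full-magnitude correction and the filter would limit-cycle instead of
resting at equilibrium.

**Error-state (indirect) Kalman filter** (`ekf_predict()`,
`ekf_update_attitude()`, `ekf_update_contact()`). The filter carries a
nominal strapdown state (quaternion, velocity, position) and the 9-dim
covariance of its error $[q_e, v_e, r_e]$ (small-angle orientation error,
velocity error, position error). The error itself is kept at zero between
updates: each measurement update estimates it, injects it into the nominal
state ($q \leftarrow q \otimes [1, q_e/2]$, renormalized), and resets it.
Prediction integrates the gyro (first order) and the gravity-compensated
specific force, and propagates $P$ with the linearized error dynamics
($\dot q_e = -[\omega]_\times q_e$, $\dot v_e = -R[a]_\times q_e$,
$\dot r_e = v_e$), symmetrizing after every step.

Measurement updates:

* *Attitude aiding*, every sample: the normalized accelerometer (gated on
  $|\,\lVert a\rVert - g\,| < 0.5\ \mathrm{m/s^2}$, i.e. quasi-static
  samples only) and magnetometer readings are treated as observations of
  the world gravity and field directions seen in the body frame
  ($H = [\,[\hat u_b]_\times\ 0\ 0\,]$). Without this aiding the 9-dim
  state has no heading observability and a biased gyro drifts without
  bound; this is the standard mechanization for a 9-axis sensor.
* *Tip pivot*, on ground-contact samples only: a planted cane tip is a
  fixed pivot, so the world tip velocity $v + R(\omega \times b)$ (sensor
  velocity plus the rotational term over the sensor-to-tip lever arm
  $b = (0,0,-\text{sensor offset})$) is measured as zero. The update uses
  the standard Kalman gain on the 9-dim state with Joseph-form covariance.
  Velocity error is coupled to tilt error through the covariance built up
  by prediction, so the pivot constraint tightens orientation as well —
  the test suite verifies the improvement on simulated pendular stance.

Noise defaults (`ekf_config()`) are matched to the simulator's sensor
model: gyro white noise 0.02 rad/s, accelerometer 0.2 m/s², a 0.01 rad/s
allowance for unmodelled bias in the orientation process noise, attitude
aiding noise 0.025 on unit direction components (the accelerometer noise
divided by g, inflated slightly for residual dynamics), tip-velocity noise
0.01 m/s. All are configuration, not constants.

`estimate_orientation()` wraps all three with a common interface; every
estimator starts from the Acc+Mag solution on the first sample and returns
one unit quaternion per sample (unit to $10^{-6}$, enforced by
renormalization at every step).

## The simulator

`simulate_cane()` produces fully analytic ground truth: the returned
angular velocity is the exact derivative of the orientation trajectory
(strapdown-integrating it recovers the quaternions to < 0.2° over 10
strides at 100 Hz), and the specific force is the exact second derivative
of the sensor position, gravity-compensated and rotated into the body
frame.

Gait activities move in the sagittal plane. During stance the cane pivots
about the planted tip (tip velocity is zero to machine precision on every
contact sample) sweeping pitch from $+\theta_0$ to $-\theta_0$
(`swing_amplitude` = $2\theta_0$, default 20°); most of the sweep is
concentrated in late stance (`sweep_fraction`, default 0.6) because a user
loads a planted cane before stepping past it. During swing the tip
translates forward (`step_length`, default 0.4 m) with a smooth lift while
pitch returns. The sagittal rate is a sum of compactly supported
raised-cosine pulses: one dominant positive mid-swing peak and smaller
negative lobes at take-off and landing — the morphology the event detector
expects. The IC trough is placed 25 ms before and the EC trough 15 ms
after the force-defined phase boundaries (landing deceleration precedes
force loading; take-off rotation follows force release), so the event
method is good but not perfect even on ideal data, as it is in reality.
Records start 40 ms into quiet stance — a recording begins with the cane
already planted and settled. The tip force is a smooth bell peaking at
40 N during contact and exactly 0 in swing, always above the 1 N labelling
threshold while in contact, so `label_from_force()` reproduces the phase
labels exactly. Stationary activities (standing, sit-to-stand) hold or
ramp the pitch with the cane planted; `stairs` adds a per-stride tip rise;
`carry` lifts the tip and oscillates pitch with an arm-swing rhythm
(~1.1 Hz) — the transport between activities in a continuous protocol, and
deliberately a failure case for the event detector.

`synthesize_imu()` corrupts the truth with the sensor model: white noise
per channel (defaults $\sigma_a = 0.2\ \mathrm{m/s^2}$,
$\sigma_\omega = 0.02\ \mathrm{rad/s}$, $\sigma_m = 0.01$), a constant
per-axis gyro bias (sd 0.01 rad/s), clipping at the sensor ranges
(±5 g, ±1500 °/s), and three transient components chosen to reflect what
an instrumented cane actually records while loaded: a short accelerometer
shock at every landing (~6 m/s², 3 samples), sporadic micro-impacts from
load shifts (~0.7/s during contact), and decaying ~9 Hz vibration rings
transmitted from the user's footsteps roughly every half stride. The white
noise levels are set so the 0.2/0.3 threshold rule is stressed but
functional on clean gait; the transients are what degrade it the way real
recordings do. All randomness flows through one seed.

`simulate_session()` chains standing, a sit-to-stand transfer, short
three-point and two-point gait bouts (a few strides each, as in a
laboratory walkway), stair steps, and carry stretches into one continuous
recording — the protocol on which phase detectors should be compared.
Orientation across segment seams is only piecewise continuous, so sessions
are for phase studies; orientation studies use single-activity trials.
`make_cohort()` draws per-subject parameters around a base setting
(defaults: stride period ±25%, swing amplitude ±30%, contact ratio ±10%,
noise scale ±30%, and ±25% on signal morphology — footstep ring frequency,
carry style, sweep shape, step length). Heterogeneity at this human scale
is what makes leave-one-subject-out evaluation meaningfully harder than
within-subject evaluation.

What the simulator does **not** emulate: magnetic disturbances, hard/soft
iron effects, out-of-sagittal cane motion (roll and yaw truth are zero
during gait, so yaw error is driven by noise and bias only), biomechanical
variability within a stride, wireless dropouts, and any validated human
kinematics. Passing orderings on this simulator show the algorithms behave
as designed under the stated conditions; they are not clinical claims.

## Evaluation protocols and problem sizes

`phase_accuracy()` is sample-wise percent agreement; `orientation_rmse()`
reports per-axis RMSE of wrapped (−180°, 180°] Euler errors, the pooled
"total" ($3N$ pooled squared errors), and the error-quaternion angle RMSE
as a convention-free alternative. `loso_cv()` trains the CNN on all
subjects but one and scores the held-out subject, per fold;
`compare_phase_methods()` runs the non-trained detectors directly on each
subject and the CNN under LOSO, so no method ever sees its test subject.

The package's own studies (test suite and `scripts/acceptance.R`) use
5-subject session cohorts (~3 000–3 800 samples per subject), 8 training
epochs, and 5–10 replicate seeds; static orientation trials are 30 s, and
the pivot-update study uses 30 s of slow pendular stance (stride 3 s,
contact ratio 0.9, full-stance sweep). These sizes keep a full run in
minutes on one core while leaving the stochastic orderings stable across
seeds.

## Numerical choices

* First-order (rectangular) quaternion integration at 100 Hz everywhere,
  matching the real-time design point; its truncation error against an
  exact integrator is far below the sensor noise floor at cane rates.
* Quaternions renormalized after every update; covariances symmetrized
  after every propagation; Joseph form for measurement updates.
* Euler extraction at gimbal lock ($|\theta| = 90^\circ$) sets yaw to 0
  and lets roll absorb the remaining rotation.
* Ties: force exactly 1 N → no contact; CNN probability exactly 0.5 → no
  contact; pooled voting count exactly half → no contact. One consistent,
  conservative rule.
* Degenerate inputs: zero-norm accelerometer or magnetometer samples raise
  an error in the closed form, skip the correction in Madgwick, and skip
  the corresponding aiding term in the EKF.
* `calibrate_static()` (gyro bias = mean over a stationary interval;
  accelerometer rescaled so the mean norm equals g) is idempotent; the
  underlying calibration procedure of the original hardware is not
  documented, so this standard static procedure is a stated stand-in.

## Limitations

* **The voting window cannot beat a crisp classifier at brisk stride
  rates.** The causal 25-sample majority delays every true transition by
  ~12 samples. On this simulator the label boundaries are pinned to the
  kinematic cues (by construction: force > 1 N exactly on contact samples,
  pivot constraint during contact), so a well-trained CNN transitions
  within ~2 samples of truth and the vote's delay costs more than its
  flicker removal recovers — at one-second strides, roughly 25 samples per
  stride. The smoother therefore *lowers* sample accuracy here, and the
  package reports that honestly; it earns its keep only when the raw
  classifier's transition region is blurrier than the vote's delay, as
  visibly unstable real-data classifiers are. Event-tolerant or
  transition-shifted scoring would separate these two effects; sample-wise
  accuracy, used throughout, does not.
* The event detector is evaluated only in its gyro-peak variant; the
  strain-gauge-assisted variant needs hardware the package does not model.
* LOSO results on five synthetic subjects carry seed-to-seed variance of a
  few percent; orderings are asserted on means over replicate seeds.
* The EKF has no magnetometer-disturbance rejection and no online bias
  state (the 9-dim error state is fixed by design); a constant bias is
  absorbed by the attitude aiding at the cost of a small steady-state
  offset.
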