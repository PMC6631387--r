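---
title: "Floating-base MAP estimation of whole-body kinematics and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating-base MAP estimation of whole-body kinematics and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapdyn)
```

## The estimation problem

A human (or any articulated body) instrumented with distributed IMUs and a
pair of force/torque (FT) sensorized shoes is modelled as a rigid
multi-body tree: $N_B$ links with spatial inertias, coupled by $n = N_B -
1$ one-degree-of-freedom joints, rooted at a *floating base* (typically the
pelvis) whose pose and 6-D velocity relative to the inertial frame are not
fixed.  The quantities of biomechanical interest — joint torques, joint
(internal) wrenches, external contact wrenches — cannot be measured
directly in vivo.  This package estimates them *simultaneously* with the
link accelerations and joint accelerations by fusing all sensors with the
rigid-body model in a Gaussian maximum-a-posteriori (MAP) framework,
sample by sample.

The stacked unknown vector per sample is
$$
d = \big(\alpha^g_0, f^x_0, \ldots, \alpha^g_{N_B-1}, f^x_{N_B-1},\;
 f_1, \ldots, f_n,\; \ddot s_1, \ldots, \ddot s_n\big) \in
 \mathbb{R}^{12 N_B + 7n},
$$
where $\alpha^g_L$ is the link's *proper sensor acceleration* — the
6-vector an ideal accelerometer/gyroscope pair rigidly attached at the
link frame reads: link-frame coordinates of the gravity-compensated origin
acceleration, followed by the angular acceleration.  $f^x_L$ is the
external wrench on link $L$, $f_J$ the wrench transmitted from parent to
child through joint $J$, and $\ddot s_J$ the joint acceleration.  Joint
torques are not part of $d$: they are recovered afterwards as the
projection $\tau_J = S_J^\top f_J$ of the joint wrench on the joint's
motion freedom subspace, with variance $S_J^\top \Sigma(f_J) S_J$.

Working with $\alpha^g$ instead of the classical body acceleration has one
decisive property: both the acceleration-propagation equation and the
Newton–Euler balance written in this variable are *agnostic to the linear
velocity of each link*, which a floating-base system cannot observe
directly.  Only angular velocities (available from the IMUs and the joint
rates) enter the model equations.

## Model equations

All 6-vectors are ordered linear block first, then angular; adjoint
transforms $X$ (motion) and $X^*$ (force) are power-invariant duals,
$X^* = X^{-\top}$.  Two row blocks per link form the dynamics system
$D(s)\,d + b_D(s, \dot s) = e_D$:

* **Acceleration propagation** (6 rows/link): for every non-base link,
  $\alpha^g_L = {}^L X_{\lambda(L)} \alpha^g_{\lambda(L)} + S_J \ddot s_J +
  c_L(s, \dot s, \omega)$, where the bias $c_L$ collects the centripetal
  and Coriolis terms
  $\big(w \times (w \times r) + 2\, w \times S_{J,\mathrm{lin}}\dot s_J,\;
  \omega_L \times S_{J,\mathrm{ang}} \dot s_J\big)$ with $w$ the parent
  angular velocity and $r$ the joint offset, both in child coordinates.
* **Newton–Euler balance** (6 rows/link):
  $M_L \alpha^g_L + (0;\omega_L) \times^* M_L (0;\omega_L) =
  f^x_L + f_J - \sum_{\mu} {}^L X^*_\mu f_\mu$, summing over the child
  joints $\mu$.

The base link has no parent joint.  Its six acceleration rows pin
$\alpha^g_B$ to the known base proper sensor acceleration supplied with
the base kinematics stream (in practice: what the pelvis IMU reads, or the
exact value in synthetic data).  This is a deliberate design choice: the
velocity-dependent part of that quantity alone (the classical
$\bar\alpha$ correction) would make the rows inconsistent even for a
static body, whose $\alpha^g$ has a linear part of norm $g = 9.81$ m/s²;
pinning to the full known value keeps $D\,d_{\text{true}} + b_D = 0$
exactly on rigid-body-consistent data, which the test suite verifies to
$10^{-8}$ at every sample.

The measurement system $Y(s)\,d + b_Y(s, \dot s) = y$ has one row block
per channel and its row count does not depend on the number of links:

* accelerometer channels transport the host link's $\alpha^g$ to the
  sensor frame through the full adjoint of the (calibrated) sensor-in-link
  transform; the lever-arm centripetal term
  ${}^S R_L\,\omega_L \times (\omega_L \times o_S)$ goes into $b_Y$;
* FT channels transport the link external wrench to the sensor frame
  through the force adjoint;
* joint-acceleration channels (Savitzky–Golay differentiated encoders or
  IK output) select single $\ddot s$ entries;
* *null-wrench channels* are zero-valued pseudo-measurements declaring a
  link contact-free.  They are on by default for links without an FT
  sensor because the dynamics rows alone cannot separate an external
  wrench on an uninstrumented link from the neighbouring joint wrenches —
  without this declaration (or a prior doing the same job) the posterior
  is weakly determined in exactly those directions.

Angular accelerations are deliberately *not* measurements in the default
layout (`imu_full = FALSE`): a gyroscope measures angular velocity, not
acceleration, so $\alpha^g$ angular parts are constrained only through the
propagation rows and the measured $\ddot s$.  Layouts for fully
instrumented synthetic rigs can switch the 6-row IMU form on.

## The Gaussian MAP solve

With $e_D \sim \mathcal N(0, \Sigma_D)$, a prior $d \sim \mathcal N(\mu_d,
\Sigma_d)$ and measurement noise $e_y \sim \mathcal N(0, \Sigma_y)$, the
posterior is Gaussian with
$$
\Sigma_{d|y} = \big(\bar\Sigma_D^{-1} + Y^\top \Sigma_y^{-1} Y\big)^{-1},
\qquad
\mu_{d|y} = \Sigma_{d|y}\big(Y^\top \Sigma_y^{-1}(y - b_Y) +
\bar\Sigma_D^{-1}\bar\mu_D\big),
$$
where the dynamics-plus-prior fusion is standard Gaussian conditioning:
$\bar\Sigma_D^{-1} = D^\top \Sigma_D^{-1} D + \Sigma_d^{-1}$ and
$\bar\Sigma_D^{-1}\bar\mu_D = \Sigma_d^{-1}\mu_d - D^\top \Sigma_D^{-1}
b_D$.  The information matrix is assembled sparse (the tree sparsity
pattern of $D$) and factorized by sparse Cholesky; a factorization failure
is reported as a non-positive-definite posterior rather than silently
regularized.  The posterior covariance is only densified on request or for
marginal blocks (torque variances), so the solve scales to the
1266-dimensional $d$ of a 67-link body.

**Covariance roles and defaults.** $\Sigma_y$ (per-channel, diagonal,
default $10^{-4}$) encodes sensor trust: lowering a channel's variance
provably lowers that channel's posterior residual, a monotonicity the
acceptance tests check empirically over 100 noise replicates.  $\Sigma_D$
(default $10^{-6}$) encodes trust in the rigid-body model; driving it to
$10^{-10}$ with noiseless consistent measurements makes the posterior mean
reproduce the inverse-dynamics oracle to machine precision.  $\Sigma_d$
(default $10^{4}$, mean zero) is the weak prior used when nothing is known
about $d$.  All are user-settable per channel/row via `sensor_layout()`
and `map_config()`.

Samples are estimated independently; the estimator applies no temporal
smoothing, so the posterior at sample $k$ is a contract depending only on
the streams at sample $k$.

## Supporting pipeline

**Sensor-position calibration.** An accelerometer at unknown link-frame
position $o_S$ satisfies, per sample, $A\,o_S = b$ with $A =
(S(\dot\omega) + S(\omega)^2) R_L$ and $b = R_S a_S - (\ddot p_L - g)$.
`estimate_sensor_position()` solves the stacked least squares by SVD.
Static samples carry no information and only amplify noise, so samples
with both $|\omega|$ and $|\dot\omega|$ below $10^{-3}$ are dropped by
default; singular values below $10^{-8}\sigma_{\max}$ are treated as zero
and trigger an unobservability error that names the null-space direction
(a single-axis spin cannot resolve the offset component along that axis —
calibration trials should spin about two non-parallel axes).

**Pairwise inverse kinematics.** Joint angles are recovered per link pair
by minimizing the squared norm of the intrinsic Z-Y-X Euler angles of the
rotation error between measured and model relative orientation, subject to
the joint limits.  The Euler sequence is a package choice (any fixed
sequence yields the same zero-residual minimizer on consistent data).  The
1-D problem is solved by golden-section refinement after a coarse grid;
within a trajectory each sample warm-starts at the previous solution and
the first sample starts from the mid-limit point, which breaks ties
between symmetric minima consistently.

**Differentiation.** Joint rates and accelerations come from a
third-order Savitzky–Golay filter (default window 9 samples at 50 Hz).
The filter reproduces polynomials up to degree 3 exactly — including at
the series ends, where the first/last full window's polynomial is
evaluated off-centre.  For band-limited signals the error is governed by
the filter's frequency response: at 1 Hz, 50 Hz sampling and window 9 the
first-derivative gain is 6.282155 versus $2\pi$, so a unit sinusoid's
derivative carries a maximum error of $1.03\times10^{-3}$ — the unit
tests pin this value against the independent `signal` package filter.
Longer windows trade this bias against noise amplification.

**Contact classification.** The offline classifier thresholds the two
shoes' vertical forces: a sample is double support when $|RF_z - LF_z|
\le T_{f_z}$, otherwise the larger side is in single support, with
$T_{f_z}$ self-tuned as the mean of the summed vertical forces times a
scale factor.  With scale 1 the mean of $RF_z + LF_z$ is approximately
body weight, which labels nearly every gait sample double support; the
scale is therefore exposed (`contact_scale`, default 1 for fidelity to
the plain rule) rather than hard-coded.  No hysteresis is applied by
default; `debounce_contacts()` offers an optional minimum-duration
filter.

**Base velocity.** During stance the supporting foot frame has zero
6-velocity, a holonomic constraint that determines the base velocity from
the joint rates: the estimate minimizes $|J_b v + J_s \dot s|^2$ over the
active contact Jacobians — one foot's 6 rows in single support, the
stacked 12 rows in double support — via SVD with relative rank tolerance
$10^{-8}$ (the single-support $J_b$ is unimodular and always solvable).

## The synthetic-data generator

No recordings ship with the package; every test runs on synthetic streams
from `simulate_trajectory()`:

* joint trajectories are sinusoids differentiated *analytically*, so the
  ground truth carries no numerical differentiation error and estimator
  error is never confounded with simulator error;
* the base either follows an explicit smooth motion ("free" mode) or is
  computed by the exact chain recursion rooted at the scheduled stance
  foot ("rooted" mode), which pins the stance frame velocity to zero by
  construction — an implementation path independent of the Jacobian
  least-squares estimator it is used to test;
* external wrenches are allocated to make the motion dynamically
  consistent: on the stance foot in rooted mode (split minimum-norm
  between the feet in double support, a reproducible choice among the
  statically indeterminate allocations), and on the base in free mode (a
  harness-style support wrench, which is why free-mode layouts place an
  FT channel on the base);
* measurements are synthesized from the sensor-frame physics (not through
  the measurement matrix, so simulator and system builder cross-check
  each other) and noise is i.i.d. Gaussian per channel, fully determined
  by one seed.

Rooted double-support samples hold the configuration at zero rates, and
stance reference poses are fixed per schedule interval, so the streams
are per-sample consistent but not globally smooth across stance
switches.  This is adequate for a per-sample estimator; what the
generator does *not* emulate are soft-tissue artifacts, sensor bias and
drift, foot roll-over and compliant ground — so green tests certify the
estimator's correctness on rigid-body-consistent data, not its robustness
to the artifacts of real recordings.

The default test body is a five-link biped (pelvis-like base, two
two-link legs, masses 3–10 kg, segment lengths 0.12–0.45 m) so the whole
suite runs in seconds; a 67-link, 66-DoF balanced-tree builder exists
purely as a scale test with no physiological fidelity claimed.  The
standard test conditions sample at 50 Hz; the oracle-equivalence check
runs 10 s (501 samples), the Monte-Carlo noise checks use 100 replicates
of a single sample, and the scale check runs 101 samples.

## Numerical choices and limitations

* Gravity is fixed at $(0, 0, -9.81)$ m/s² (z up) and configurable in
  every kinematics/dynamics entry point.
* Angles are radians everywhere inside the package; degrees appear only
  at I/O boundaries if a caller puts them there.
* Joint numbering follows the topology: joint $J$ shares the index of its
  child link, links are numbered breadth-first from the base; the
  `d_index()` slice map is the single source of truth for the
  serialization and is tested as a bijection.
* The URDF reader covers the subset relevant here — links with inertial
  blocks, revolute/prismatic/continuous joints with limits — and rejects
  cycles, duplicate parents, multi-DoF joints and missing inertias with
  errors naming the offending element.  Meshes, sensors and transmissions
  are ignored; closed kinematic loops are out of scope.
* Aerial phases (no contact) leave the base-velocity stage undefined;
  the estimator then requires the base velocity to be supplied, and the
  base *position* is never reconstructed (no drift correction).
* Real-time operation, non-Gaussian noise models and inertial-parameter
  estimation are out of scope; anthropometric model synthesis from body
  mass and landmarks is not provided — models come from URDF or the
  builders.

## A minimal session

```{r example, eval = FALSE}
model <- make_biped_model()
spec <- trajectory_spec(model,
  base = list(mode = "rooted"),
  schedule = data.frame(label = c("double", "right", "double", "left"),
                        duration = c(0.3, 0.5, 0.3, 0.5)),
  frames = list(right = 4L, left = 5L),
  joints = data.frame(amp = 0.25, freq = 0.8, phase = c(0, pi, 1, 2),
                      offset = c(0, 0, -0.5, -0.5)),
  duration = 1.6, rate = 50, seed = 1)
gt <- simulate_trajectory(spec)
layout <- sensor_layout(model, ft_links = c(4L, 5L))
streams <- generate_measurements(gt, layout,
                                 noise_sd = c(imu = 0.01), seed = 1)
fit <- estimate_dynamics(model, streams)
summary(fit)
plot(fit)
```
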