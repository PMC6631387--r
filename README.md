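# mapdyn

Simultaneous floating-base estimation of whole-body kinematics and
dynamics from wearable sensors.

Joint torques, joint (internal) wrenches and external contact wrenches
cannot be measured directly on a moving human. `mapdyn` estimates them —
together with the link accelerations and joint accelerations — for an
articulated rigid multi-body model with a floating base (e.g. the
pelvis), by fusing distributed IMUs, force/torque (FT) sensorized shoes
and differentiated joint encoders with the rigid-body model in a Gaussian
maximum-a-posteriori framework. It is aimed at biomechanics and
physical human–robot interaction researchers who need whole-body torque
estimates from wearable data, without switching the model root between
tasks as fixed-base pipelines require.

## The estimator in brief

Per sample, the unknowns are stacked as

    d = (alpha_0, fx_0, ..., alpha_{NB-1}, fx_{NB-1},
         f_1, ..., f_n, sdd_1, ..., sdd_n)  in  R^(12 NB + 7 n)

where `alpha_L` is the link's *proper sensor acceleration* (the
gravity-compensated 6-acceleration an IMU on the link reads), `fx_L` the
external wrench, `f_J` the joint wrench and `sdd_J` the joint
acceleration. Two linear systems constrain `d`: the model rows
`D(s) d + b_D(s, sdot) = e_D` (acceleration propagation through every
joint plus the Newton–Euler balance of every link, all agnostic to link
linear velocities) and the measurement rows `Y(s) d + b_Y = y` (IMU, FT,
joint-acceleration and null-wrench channels). With Gaussian model noise
`Sigma_D`, prior `(mu_d, Sigma_d)` and sensor covariances `Sigma_y`, the
posterior is Gaussian:

    Sigma_post = (D' inv(Sigma_D) D + inv(Sigma_d) + Y' inv(Sigma_y) Y)^-1
    mu_post    = Sigma_post (Y' inv(Sigma_y) (y - b_Y)
                             + inv(Sigma_d) mu_d - D' inv(Sigma_D) b_D)

solved by sparse Cholesky per sample. Joint torques are the projection
`tau_J = S_J' f_J` with variance `S_J' Sigma(f_J) S_J`.

The supporting pipeline is included: a URDF-subset reader, least-squares
calibration of sensor positions from IMU spin trials, link-pairwise
inverse kinematics with Savitzky–Golay differentiation, vertical-force
contact classification (double / right / left support), and
contact-constrained base-velocity estimation. A rigid-body-consistent
synthetic-data simulator generates every stream needed to exercise the
full pipeline without recordings.

## Worked example

Simulate a short walking-like trial on the built-in five-link biped
(double → right stance → double → left stance), synthesize noisy IMU
streams plus exact FT and joint-acceleration channels, and estimate:

```r
library(mapdyn)
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
streams <- generate_measurements(gt, layout, noise_sd = c(imu = 0.01), seed = 1)
fit <- estimate_dynamics(model, streams)
summary(fit)
```

```
MAP dynamics estimate over 81 samples

Joint torque RMS [N m]:
 right_hip   left_hip right_knee  left_knee
    8.0974    10.5543    38.6133    21.8070

Mean posterior torque SD [N m]:
 right_hip   left_hip right_knee  left_knee
    0.0218     0.0217     0.0110     0.0110

Measurement residual RMS by channel kind:
         ft         imu        jacc null_wrench
   1.10e-06    9.84e-03    2.02e-03    3.42e-07

Contact classification:
double  right   left
    31     25     25
```

The torque RMS rows are the estimated joint-torque trajectories (knees
carry most of the load in stance); the posterior SDs quantify how tightly
the sensors plus model pin each torque (about 0.02 N m here); the IMU
residual RMS sits at the injected 0.01 m/s² noise level while the exact
channels are reproduced to ~1e-6; and the contact table shows the
classified support phases driving the base-velocity constraint. Against
the inverse-dynamics oracle on this trial,
`max(abs(coef(fit) - gt$tau))` is 0.022 N m.

`coef(fit)` returns the torque matrix, `residuals(fit)`/`fitted(fit)` the
measurement-space decomposition, `plot(fit)` the torque trajectories and
`simulate(fit, nsim, sample = k)` posterior draws of `d`.

A thin command-line front end over the same functions lives at
`inst/cli/mapdyn.R` (subcommands `calibrate`, `ik`, `classify`,
`simulate`).

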