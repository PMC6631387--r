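# Shared fixtures, all generated in code.

random_rotation <- function() {
  v <- stats::rnorm(3)
  rot_axis_angle(v / sqrt(sum(v^2)), stats::runif(1, -pi, pi))
}

random_transform <- function() {
  spatial_transform(random_rotation(), stats::runif(3, -0.5, 0.5))
}

random_state <- function(model, vel = TRUE, acc = TRUE) {
  n <- n_joints(model)
  system_state(random_rotation(), stats::runif(3, -1, 1),
               s = stats::runif(n, -1, 1),
               base_vel = if (vel) stats::rnorm(6) * 0.5 else numeric(6),
               s_dot = if (vel) stats::rnorm(n) * 0.5 else numeric(n),
               base_acc = if (acc) stats::rnorm(6) * 0.5 else numeric(6),
               s_ddot = if (acc) stats::rnorm(n) * 0.5 else numeric(n))
}

# A two-link URDF with one revolute joint (used by the parser tests).
urdf_two_link <- function() {
  '<robot name="two_link">
     <link name="base">
       <inertial>
         <origin xyz="0 0 0.05" rpy="0 0 0"/>
         <mass value="4.0"/>
         <inertia ixx="0.05" ixy="0" ixz="0" iyy="0.04" iyz="0" izz="0.03"/>
       </inertial>
     </link>
     <link name="arm">
       <inertial>
         <origin xyz="0 0 -0.2" rpy="0.1 0 0"/>
         <mass value="1.5"/>
         <inertia ixx="0.01" ixy="0.001" ixz="0" iyy="0.012" iyz="0" izz="0.002"/>
       </inertial>
     </link>
     <joint name="shoulder" type="revolute">
       <parent link="base"/>
       <child link="arm"/>
       <origin xyz="0 0.1 -0.05" rpy="0 0.2 0"/>
       <axis xyz="0 1 0"/>
       <limit lower="-1.5" upper="1.5"/>
     </joint>
   </robot>'
}

# Calibration trial: link spinning about two non-parallel axes, sensor
# rigidly mounted at offset o_S with the link orientation.  Analytic
# kinematics, optional accelerometer noise.
make_calibration_samples <- function(N, o_S, noise = 0, seed = 1L,
                                     two_axis = TRUE) {
  set.seed(seed)
  tt <- seq(0, 10, length.out = N)
  g <- default_gravity()
  rows <- lapply(tt, function(t) {
    th1 <- 1.2 * sin(2 * pi * 0.5 * t)
    th1d <- 1.2 * 2 * pi * 0.5 * cos(2 * pi * 0.5 * t)
    th1dd <- -1.2 * (2 * pi * 0.5)^2 * sin(2 * pi * 0.5 * t)
    if (two_axis) {
      th2 <- 0.8 * sin(2 * pi * 0.3 * t + 1)
      th2d <- 0.8 * 2 * pi * 0.3 * cos(2 * pi * 0.3 * t + 1)
      th2dd <- -0.8 * (2 * pi * 0.3)^2 * sin(2 * pi * 0.3 * t + 1)
    } else th2 <- th2d <- th2dd <- 0
    R <- mapdyn:::rot_x(th1) %*% mapdyn:::rot_y(th2)
    ex <- c(1, 0, 0)
    ey_r <- as.numeric(mapdyn:::rot_x(th1) %*% c(0, 1, 0))
    w <- ex * th1d + ey_r * th2d
    dw <- ex * th1dd + ey_r * th2dd +
      mapdyn:::cross3(ex * th1d, ey_r) * th2d
    pdd <- c(0.1 * sin(t), 0, 0)
    o_I <- as.numeric(R %*% o_S)
    pddS <- pdd + mapdyn:::cross3(dw, o_I) +
      mapdyn:::cross3(w, mapdyn:::cross3(w, o_I))
    aS <- as.numeric(t(R) %*% (pddS - g)) + stats::rnorm(3, 0, noise)
    ql <- rot_to_quat(R)
    data.frame(ax = aS[1], ay = aS[2], az = aS[3],
               wx = w[1], wy = w[2], wz = w[3],
               dwx = dw[1], dwy = dw[2], dwz = dw[3],
               qlw = ql[1], qlx = ql[2], qly = ql[3], qlz = ql[4],
               qsw = ql[1], qsx = ql[2], qsy = ql[3], qsz = ql[4],
               alx = pdd[1], aly = pdd[2], alz = pdd[3])
  })
  do.call(rbind, rows)
}

# Free-base biped trajectory + fully instrumented layout (FT on the base
# because the balancing wrench of the prescribed free motion acts there).
biped_free_setup <- function(duration = 1, rate = 50, seed = 3,
                             var = 1e-4, imu_offsets = FALSE) {
  mod <- make_biped_model()
  spec <- trajectory_spec(mod,
    joints = data.frame(amp = c(0.2, 0.2, -0.25, -0.25),
                        freq = c(0.5, 0.7, 0.6, 0.4),
                        phase = c(0, 1, 2, 3), offset = c(0, 0, -0.8, -0.8)),
    base = list(mode = "free", pos0 = c(0, 0, 1),
                lin_amp = c(0.05, 0.03, 0.02), lin_freq = c(0.4, 0.3, 0.5),
                ang_axis = c(0, 0, 1), ang_amp = 0.3, ang_freq = 0.4),
    duration = duration, rate = rate, seed = seed)
  gt <- simulate_trajectory(spec)
  Ts <- if (imu_offsets)
    lapply(seq_len(n_links(mod)), function(i)
      spatial_transform(rot_axis_angle(c(1, 0, 0), 0.3), c(0.05, 0.02, -0.1)))
  else NULL
  lay <- sensor_layout(mod, imu_transforms = Ts, ft_links = c(1L, 4L, 5L),
                       var_imu = var, var_ft = var, var_jacc = var,
                       var_null = var)
  list(model = mod, gt = gt, layout = lay)
}

tight_layout <- function(layout, var = 1e-10) {
  for (i in seq_along(layout$channels)) layout$channels[[i]]$var <- var
  layout
}
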