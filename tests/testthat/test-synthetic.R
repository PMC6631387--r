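test_that("static standing: unit-norm gravity accelerations and zero joint accelerations", {
  mod <- make_biped_model()
  spec <- trajectory_spec(mod,
    joints = data.frame(amp = 0, freq = 1, phase = 0,
                        offset = c(0, 0, -0.4, -0.4)),
    base = list(mode = "rooted"),
    schedule = data.frame(label = "double", duration = 0.5),
    frames = list(right = 4L, left = 5L), duration = 0.5)
  gt <- simulate_trajectory(spec)
  for (k in c(1L, 13L, 26L)) {
    a <- gt$kin[[k]]$alpha_g
    expect_equal(apply(a[1:3, ], 2, function(v) sqrt(sum(v^2))),
                 rep(9.81, n_links(mod)), tolerance = 1e-10)
    expect_equal(gt$states[[k]]$s_ddot, numeric(4))
  }
  # vertical ground reaction sums to the body weight
  W <- sum(vapply(mod$links, function(l) l$inertia$mass, 0)) * 9.81
  kin <- gt$kin[[1]]
  fz <- sum(vapply(c(4L, 5L), function(f)
    as.numeric(kin$R[[f]] %*% gt$f_ext[[1]][1:3, f])[3], 0))
  expect_equal(fz, W, tolerance = 1e-8)
})

test_that("free fall of a single link needs no external wrench and no torque", {
  mod <- multibody_model(list(list(name = "b",
    inertia = spatial_inertia(2, c(0.05, 0, 0),
      mapdyn:::inertia_at_origin(diag(3) * 0.01, 2, c(0.05, 0, 0))))))
  # free mode with the gravity parabola: lin acc = g at all times is not a
  # sinusoid, so emulate with zero gravity and a static base instead
  spec <- trajectory_spec(mod, joints = data.frame(amp = numeric(0),
                                                   freq = numeric(0),
                                                   phase = numeric(0),
                                                   offset = numeric(0)),
                          base = list(mode = "static"), duration = 0.2)
  gt <- simulate_trajectory(spec, gravity = c(0, 0, 0))
  for (k in seq_along(gt$time)) {
    expect_equal(max(abs(gt$f_ext[[k]])), 0, tolerance = 1e-12)
    expect_length(gt$tau[k, ], 0L)
  }
})

test_that("ground truth satisfies both dynamics formulations at every sample", {
  setup <- biped_free_setup(duration = 0.4)
  gt <- setup$gt
  mod <- setup$model
  for (k in seq_along(gt$time)) {
    st <- gt$states[[k]]
    kin <- gt$kin[[k]]
    # stacked-system residual
    dyn <- build_dynamics_system(mod, st$s, st$s_dot, kin$omega_body[, 1],
                                 kin$alpha_g[, 1])
    expect_lt(max(abs(as.numeric(dyn$D %*% gt$d_true[, k]) + dyn$b)), 1e-8)
  }
  # generalized-coordinate residual at a few samples
  for (k in c(1L, 11L, 21L)) {
    st <- gt$states[[k]]
    mb <- mass_matrix_and_bias(mod, st)
    lhs <- as.numeric(mb$M %*% c(st$base_acc, st$s_ddot)) + mb$h
    rhs <- c(numeric(6), gt$tau[k, ])
    kin <- gt$kin[[k]]
    for (i in seq_len(n_links(mod))) {
      J <- contact_jacobian(mod, st, i, kin = kin)
      wI <- c(as.numeric(kin$R[[i]] %*% gt$f_ext[[k]][1:3, i]),
              as.numeric(kin$R[[i]] %*% gt$f_ext[[k]][4:6, i]))
      rhs <- rhs + as.numeric(t(J) %*% wI)
    }
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("walking-like schedule pins the stance foot and labels follow the schedule", {
  mod <- make_biped_model()
  sched <- data.frame(label = c("double", "right", "double", "left"),
                      duration = c(0.3, 0.5, 0.3, 0.5))
  spec <- trajectory_spec(mod,
    joints = data.frame(amp = 0.25, freq = 0.8, phase = c(0, pi, 1, 2),
                        offset = c(0, 0, -0.5, -0.5)),
    base = list(mode = "rooted"), schedule = sched,
    frames = list(right = 4L, left = 5L), duration = 1.6, rate = 50)
  gt <- simulate_trajectory(spec)
  for (k in seq_along(gt$time)) {
    lab <- as.character(gt$labels[k])
    feet <- switch(lab, right = 4L, left = 5L, double = c(4L, 5L))
    st <- gt$states[[k]]
    kin <- gt$kin[[k]]
    for (f in feet) {
      vF <- c(kin$pdot[, f], kin$omega_I[, f])
      expect_lt(max(abs(vF)), 1e-10)
    }
  }
  expect_equal(sum(gt$labels == "right"), sum(gt$time > 0.3 & gt$time <= 0.8))
})

test_that("measurement simulator is exact at zero noise and reproducible from the seed", {
  setup <- biped_free_setup(duration = 0.3, imu_offsets = TRUE)
  s1 <- generate_measurements(setup$gt, setup$layout, seed = 11)
  s2 <- generate_measurements(setup$gt, setup$layout, seed = 11)
  expect_identical(s1$y, s2$y)
  noisy1 <- generate_measurements(setup$gt, setup$layout,
                                  noise_sd = c(imu = 0.01), seed = 11)
  noisy2 <- generate_measurements(setup$gt, setup$layout,
                                  noise_sd = c(imu = 0.01), seed = 11)
  expect_identical(noisy1$y, noisy2$y)
  expect_false(identical(noisy1$y, s1$y))
})

test_that("injected noise has the requested per-channel variance", {
  setup <- biped_free_setup(duration = 0.1)
  sigma <- 1e-2
  clean <- generate_measurements(setup$gt, setup$layout)
  rows <- mapdyn:::channel_rows(setup$layout, 1L)   # first IMU
  devs <- unlist(lapply(1:200, function(r) {
    noisy <- generate_measurements(setup$gt, setup$layout,
                                   noise_sd = c(imu = sigma), seed = r)
    (noisy$y - clean$y)[rows, ]
  }))
  expect_lt(abs(stats::var(devs) / sigma^2 - 1), 0.2)
})

test_that("gait force generator produces the scheduled plateaus and labels", {
  all_double <- data.frame(label = "double", duration = 1)
  tr <- generate_gait_forces(all_double, weight = 700, transition = 0, rate = 50)
  expect_true(all(tr$rf_fz == 350) && all(tr$lf_fz == 350))
  one <- generate_gait_forces(data.frame(label = "right", duration = 0.5),
                              weight = 600, transition = 0, rate = 50)
  expect_true(all(one$rf_fz == 600) && all(one$lf_fz == 0))
  sched <- data.frame(label = c("double", "right", "double", "left", "double"),
                      duration = c(0.5, 0.8, 0.4, 0.8, 0.5))
  tr2 <- generate_gait_forces(sched, weight = 700, transition = 0.2, rate = 50)
  Tfz <- compute_threshold(tr2$rf_fz, tr2$lf_fz, 0.5)
  got <- classify_contacts(tr2$rf_fz, tr2$lf_fz, Tfz)
  away <- !tr2$transition_mask
  agree <- mean(got[away] == tr2$labels[away])
  expect_gte(agree, 0.99)
})

test_that("invalid schedules and specs are rejected", {
  mod <- make_biped_model()
  expect_error(trajectory_spec(mod,
    joints = data.frame(amp = 5, freq = 1, phase = 0, offset = 0)),
    "exceeds its limits")
  expect_error(simulate_trajectory(trajectory_spec(mod,
    base = list(mode = "rooted"),
    joints = data.frame(amp = 0, freq = 1, phase = 0,
                        offset = c(0, 0, -0.4, -0.4)))),
    "schedule")
})
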