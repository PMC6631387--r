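test_that("the d serialization is a bijection with the documented layout", {
  mod <- make_biped_model()
  nb <- n_links(mod); n <- n_joints(mod)
  expect_equal(d_length(mod), 12 * nb + 7 * n)
  idx <- c(unlist(lapply(seq_len(nb), function(i)
    c(d_index(mod, "alpha", i), d_index(mod, "fx", i)))),
    unlist(lapply(seq_len(n), function(j) d_index(mod, "fjoint", j))),
    vapply(seq_len(n), function(j) d_index(mod, "sddot", j), 0L))
  expect_equal(sort(idx), seq_len(d_length(mod)))   # partition, no overlap
  expect_equal(d_index(mod, "alpha", 1), 1:6)
})

test_that("proper sensor/body acceleration conversion round-trips and statics read 9.81", {
  set.seed(41)
  for (i in 1:10) {
    alpha <- rnorm(6); v <- rnorm(3); w <- rnorm(3)
    a <- proper_body_from_sensor(alpha, v, w)
    expect_equal(proper_sensor_from_body(a, v, w), alpha, tolerance = 1e-12)
    expect_equal(a[4:6], alpha[4:6])   # angular part untouched
  }
  # zero velocity: correction vanishes
  expect_equal(proper_body_from_sensor(1:6, c(0, 0, 0), c(0, 0, 0)),
               as.numeric(1:6))
  # a static link's proper sensor acceleration reads minus gravity
  mod <- make_biped_model()
  st <- system_state(random_rotation(), c(0, 0, 1), s = c(0.1, 0, -0.5, -0.4))
  kin <- link_kinematics(mod, st)
  for (i in seq_len(n_links(mod)))
    expect_equal(sqrt(sum(kin$alpha_g[1:3, i]^2)), 9.81, tolerance = 1e-10)
})

test_that("dynamics matrix has the documented shape and base block structure", {
  mod <- make_biped_model()
  nb <- n_links(mod); n <- n_joints(mod)
  st <- random_state(mod)
  kin <- link_kinematics(mod, st)
  dyn <- build_dynamics_system(mod, st$s, st$s_dot, kin$omega_body[, 1],
                               kin$alpha_g[, 1])
  expect_equal(dim(dyn$D), c(12 * nb, 12 * nb + 7 * n))
  D <- as.matrix(dyn$D)
  # base acceleration rows touch only the base alpha slice
  acc_rows <- 1:6
  expect_equal(D[acc_rows, d_index(mod, "alpha", 1)], -diag(6))
  other <- setdiff(seq_len(ncol(D)), d_index(mod, "alpha", 1))
  expect_equal(max(abs(D[acc_rows, other])), 0)
  # base balance rows carry no parent joint wrench block of their own
  ne_rows <- 7:12
  expect_equal(D[ne_rows, d_index(mod, "fx", 1)], -diag(6))
})

test_that("simulated ground truth satisfies D d + b_D = 0 and Y d + b_Y = y", {
  setup <- biped_free_setup(duration = 0.5, imu_offsets = TRUE)
  gt <- setup$gt
  streams <- generate_measurements(gt, setup$layout)
  for (k in c(1L, 10L, 26L)) {
    st <- gt$states[[k]]
    kin0 <- mapdyn:::body_kinematics(setup$model, st$s, st$s_dot,
                                     gt$kin[[k]]$omega_body[, 1])
    dyn <- build_dynamics_system(setup$model, st$s, st$s_dot,
                                 gt$kin[[k]]$omega_body[, 1],
                                 gt$kin[[k]]$alpha_g[, 1], kin0 = kin0)
    expect_lt(max(abs(as.numeric(dyn$D %*% gt$d_true[, k]) + dyn$b)), 1e-8)
    meas <- build_measurement_system(setup$model, setup$layout, st$s,
                                     st$s_dot, kin0 = kin0)
    expect_lt(max(abs(as.numeric(meas$Y %*% gt$d_true[, k]) + meas$b -
                        streams$y[, k])), 1e-10)
  }
})

test_that("IMU and FT blocks reduce to identity selections for trivially mounted sensors", {
  mod <- make_biped_model()
  lay <- sensor_layout(mod, imu_links = 2L, imu_full = TRUE,
                       ft_links = 4L, null_wrench_links = integer(0),
                       jacc_joints = integer(0))
  meas <- build_measurement_system(mod, lay, numeric(4), numeric(4))
  Y <- as.matrix(meas$Y)
  expect_equal(Y[1:6, d_index(mod, "alpha", 2L)], diag(6))
  expect_equal(Y[7:12, d_index(mod, "fx", 4L)], diag(6))
  expect_equal(meas$b, numeric(12))
})

test_that("MAP recovers the ground truth from noiseless consistent measurements", {
  setup <- biped_free_setup(duration = 0.3, imu_offsets = TRUE)
  gt <- setup$gt
  lay <- tight_layout(setup$layout)
  streams <- generate_measurements(gt, lay)
  k <- 7L
  st <- gt$states[[k]]
  dyn <- build_dynamics_system(setup$model, st$s, st$s_dot,
                               gt$kin[[k]]$omega_body[, 1],
                               gt$kin[[k]]$alpha_g[, 1])
  meas <- build_measurement_system(setup$model, lay, st$s, st$s_dot,
                                   base_omega = gt$kin[[k]]$omega_body[, 1])
  est <- map_solve(meas$Y, meas$b, streams$y[, k], meas$sigma, dyn$D, dyn$b,
                   map_prior(Sigma_D = 1e-10))
  scale <- pmax(abs(gt$d_true[, k]), 1)
  expect_lt(max(abs(est$mean - gt$d_true[, k]) / scale), 1e-6)
})

test_that("with no sensor trust the posterior collapses to the dynamics-plus-prior solution", {
  setup <- biped_free_setup(duration = 0.3)
  gt <- setup$gt
  streams <- generate_measurements(gt, setup$layout)
  k <- 3L
  st <- gt$states[[k]]
  dyn <- build_dynamics_system(setup$model, st$s, st$s_dot,
                               gt$kin[[k]]$omega_body[, 1],
                               gt$kin[[k]]$alpha_g[, 1])
  meas <- build_measurement_system(setup$model, setup$layout, st$s, st$s_dot,
                                   base_omega = gt$kin[[k]]$omega_body[, 1])
  prior <- map_prior(Sigma_D = 1e-6, Sigma_d = 1e4)
  est <- map_solve(meas$Y, meas$b, streams$y[, k], 1e12, dyn$D, dyn$b, prior)
  # independent dense weighted least squares on [D; prior]
  D <- as.matrix(dyn$D)
  A <- rbind(D / sqrt(1e-6), diag(ncol(D)) / sqrt(1e4))
  rhs <- c(-dyn$b / sqrt(1e-6), numeric(ncol(D)))
  mu_ref <- qr.solve(A, rhs)
  expect_equal(est$mean, mu_ref, tolerance = 1e-4)
})

test_that("posterior covariance is SPD and contracts below the prior on measured entries", {
  setup <- biped_free_setup(duration = 0.3)
  gt <- setup$gt
  streams <- generate_measurements(gt, setup$layout)
  k <- 2L
  st <- gt$states[[k]]
  dyn <- build_dynamics_system(setup$model, st$s, st$s_dot,
                               gt$kin[[k]]$omega_body[, 1],
                               gt$kin[[k]]$alpha_g[, 1])
  meas <- build_measurement_system(setup$model, setup$layout, st$s, st$s_dot,
                                   base_omega = gt$kin[[k]]$omega_body[, 1])
  est <- map_solve(meas$Y, meas$b, streams$y[, k], meas$sigma, dyn$D, dyn$b,
                   map_prior(), compute_cov = TRUE)
  expect_equal(est$cov, t(est$cov), tolerance = 1e-10)
  ev <- eigen(est$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(all(diag(est$cov) <= 1e4 + 1e-8))
  # posterior is the exact minimizer of the stacked weighted least squares
  A <- rbind(as.matrix(meas$Y) / sqrt(meas$sigma),
             as.matrix(dyn$D) / sqrt(1e-6),
             diag(ncol(dyn$D)) / sqrt(1e4))
  rhs <- c((streams$y[, k] - meas$b) / sqrt(meas$sigma),
           -dyn$b / sqrt(1e-6), numeric(ncol(dyn$D)))
  expect_equal(est$mean, qr.solve(A, rhs), tolerance = 1e-8)
})

test_that("torque extraction projects joint wrenches onto the motion subspace", {
  mod <- make_biped_model()   # all joints about y
  est <- structure(list(mean = numeric(d_length(mod)), cov = NULL,
                        n = d_length(mod)), class = "gaussian_estimate")
  est$mean[d_index(mod, "fjoint", 1L)] <- c(0, 0, 0, 0, 5, 0)
  est$cov <- diag(0.25, d_length(mod))
  tq <- extract_torques(est, mod)
  expect_equal(tq$tau, c(5, 0, 0, 0))
  expect_equal(tq$var, rep(0.25, 4))
})

test_that("permuting sibling numbering leaves the torques invariant", {
  mod <- make_biped_model()
  # same tree with the two legs enumerated in the opposite order
  perm <- c(1L, 3L, 2L, 5L, 4L)   # link i of mod2 = link perm[i] of mod
  links2 <- lapply(perm, function(i) mod$links[[i]])
  joints2 <- list(
    model_joint("left_hip", 1L, 2L, "revolute", c(0, 1, 0), c(0, 0.12, 0),
                limits = c(-2, 2)),
    model_joint("right_hip", 1L, 3L, "revolute", c(0, 1, 0), c(0, -0.12, 0),
                limits = c(-2, 2)),
    model_joint("left_knee", 2L, 4L, "revolute", c(0, 1, 0), c(0, 0, -0.45),
                limits = c(-2.3, 0.1)),
    model_joint("right_knee", 3L, 5L, "revolute", c(0, 1, 0), c(0, 0, -0.45),
                limits = c(-2.3, 0.1)))
  mod2 <- multibody_model(links2, joints2)
  jperm <- c(2L, 1L, 4L, 3L)      # joint j of mod2 = joint jperm[j] of mod

  run_fit <- function(model, ft, seed) {
    spec <- trajectory_spec(model,
      joints = data.frame(amp = 0.2, freq = 0.5, phase = c(0, 1, 2, 3),
                          offset = c(0, 0, -0.5, -0.5)),
      base = list(mode = "free", lin_amp = c(0.03, 0, 0.02),
                  ang_axis = c(0, 1, 0), ang_amp = 0.2),
      duration = 0.2, rate = 50, seed = seed)
    gt <- simulate_trajectory(spec)
    lay <- tight_layout(sensor_layout(model, ft_links = ft))
    fit <- estimate_dynamics(model, generate_measurements(gt, lay),
                             layout = lay,
                             config = map_config(Sigma_D = 1e-10))
    fit$tau
  }
  # swap the per-leg trajectory phases consistently with the renumbering
  spec_phases <- c(0, 1, 2, 3)
  tau1 <- run_fit(mod, c(1L, 4L, 5L), 1)
  spec2 <- trajectory_spec(mod2,
    joints = data.frame(amp = 0.2, freq = 0.5, phase = spec_phases[jperm],
                        offset = c(0, 0, -0.5, -0.5)),
    base = list(mode = "free", lin_amp = c(0.03, 0, 0.02),
                ang_axis = c(0, 1, 0), ang_amp = 0.2),
    duration = 0.2, rate = 50, seed = 1)
  gt2 <- simulate_trajectory(spec2)
  lay2 <- tight_layout(sensor_layout(mod2, ft_links = c(1L, 4L, 5L)))
  fit2 <- estimate_dynamics(mod2, generate_measurements(gt2, lay2),
                            layout = lay2,
                            config = map_config(Sigma_D = 1e-10))
  expect_equal(fit2$tau[, jperm], tau1, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("map_solve rejects invalid covariances and reports singular systems", {
  mod <- make_biped_model()
  st <- system_state(s = numeric(4))
  kin <- link_kinematics(mod, st)
  dyn <- build_dynamics_system(mod, st$s, st$s_dot, c(0, 0, 0),
                               kin$alpha_g[, 1])
  lay <- sensor_layout(mod, ft_links = c(1L, 4L, 5L))
  meas <- build_measurement_system(mod, lay, st$s, st$s_dot)
  y <- numeric(lay$n_rows)
  expect_error(map_solve(meas$Y, meas$b, y, -1, dyn$D, dyn$b), "positive")
})
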