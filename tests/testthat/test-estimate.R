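test_that("full pipeline torques match the inverse-dynamics oracle on noiseless data", {
  setup <- biped_free_setup(duration = 0.5, imu_offsets = TRUE)
  lay <- tight_layout(setup$layout)
  streams <- generate_measurements(setup$gt, lay)
  fit <- estimate_dynamics(setup$model, streams, layout = lay,
                           config = map_config(Sigma_D = 1e-10))
  expect_s3_class(fit, "map_dynamics")
  expect_lt(max(abs(fit$tau - setup$gt$tau)), 1e-6)
  # posterior torque SDs are finite and positive
  expect_true(all(fit$tau_sd > 0))
  # residuals of the posterior mean are tiny on consistent data
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("noisy torque estimates fall within three posterior SDs of the oracle", {
  setup <- biped_free_setup(duration = 0.2)
  noise <- c(imu = 0.01, ft = 0.01, jacc = 0.01)
  streams <- generate_measurements(setup$gt, setup$layout,
                                   noise_sd = noise, seed = 99)
  fit <- estimate_dynamics(setup$model, streams)
  z <- abs(fit$tau - setup$gt$tau) / fit$tau_sd
  expect_lt(stats::quantile(z, 0.99), 5)   # allow rare 3-sigma exceedances
  expect_gt(mean(z <= 3), 0.95)
})

test_that("a single-sample run equals calling the stages manually", {
  setup <- biped_free_setup(duration = 0.1)
  streams <- generate_measurements(setup$gt, setup$layout)
  fit <- estimate_dynamics(setup$model, streams)
  k <- 1L
  st <- setup$gt$states[[k]]
  kin0 <- mapdyn:::body_kinematics(setup$model, st$s, st$s_dot,
                                   streams$base_omega[, k])
  dyn <- build_dynamics_system(setup$model, st$s, st$s_dot,
                               streams$base_omega[, k],
                               streams$base_alpha[, k], kin0 = kin0)
  meas <- build_measurement_system(setup$model, setup$layout, st$s, st$s_dot,
                                   kin0 = kin0)
  est <- map_solve(meas$Y, meas$b, streams$y[, k], meas$sigma, dyn$D, dyn$b,
                   map_prior())
  expect_equal(fit$mu[, k], est$mean, tolerance = 1e-10)
  expect_equal(fit$tau[k, ], extract_torques(est, setup$model)$tau,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("decreasing a channel's variance decreases that channel's posterior residual", {
  setup <- biped_free_setup(duration = 0.1)
  streams <- generate_measurements(setup$gt, setup$layout,
                                   noise_sd = c(imu = 0.05, ft = 0.05,
                                                jacc = 0.05), seed = 5)
  ch <- 2L   # an IMU channel
  rows <- mapdyn:::channel_rows(setup$layout, ch)
  res_for <- function(v) {
    lay <- setup$layout
    lay$channels[[ch]]$var <- v
    fit <- estimate_dynamics(setup$model, streams, layout = lay)
    sqrt(mean(residuals(fit)[rows, ]^2))
  }
  r <- vapply(c(1e-2, 1e-3, 1e-4), res_for, 0)
  expect_true(all(diff(r) < 0))
})

test_that("contact-stage integration: labels drive the base-velocity constraint choice", {
  mod <- make_biped_model()
  sched <- data.frame(label = c("double", "right", "double", "left"),
                      duration = c(0.2, 0.4, 0.2, 0.4))
  spec <- trajectory_spec(mod,
    joints = data.frame(amp = 0.2, freq = 0.8, phase = c(0, pi, 1, 2),
                        offset = c(0, 0, -0.5, -0.5)),
    base = list(mode = "rooted"), schedule = sched,
    frames = list(right = 4L, left = 5L), duration = 1.2, rate = 50)
  gt <- simulate_trajectory(spec)
  lay <- sensor_layout(mod, ft_links = c(4L, 5L))
  streams <- generate_measurements(gt, lay)
  fit <- estimate_dynamics(mod, streams)
  expect_equal(fit$labels, gt$labels)
  # estimated base velocity equals the simulated one on every sample
  bv_true <- vapply(gt$states, `[[`, numeric(6), "base_vel")
  expect_lt(max(abs(fit$base_vel - bv_true)), 1e-8)
})

test_that("S3 methods expose the fit consistently", {
  setup <- biped_free_setup(duration = 0.1)
  streams <- generate_measurements(setup$gt, setup$layout)
  fit <- estimate_dynamics(setup$model, streams)
  expect_equal(coef(fit), fit$tau)
  expect_equal(fitted(fit) + residuals(fit), streams$y, tolerance = 1e-12)
  expect_output(print(fit), "Floating-base MAP")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.map_dynamics")
  expect_output(print(sm), "torque RMS")
  draws <- simulate(fit, nsim = 5, seed = 1, sample = 2L)
  expect_equal(dim(draws), c(d_length(setup$model), 5L))
  draws2 <- simulate(fit, nsim = 5, seed = 1, sample = 2L)
  expect_equal(draws, draws2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("CSV round-trips preserve the stream contents", {
  tmp <- withr::local_tempdir()
  mod <- make_biped_model()
  st <- system_state(s = c(0.2, -0.1, -0.5, -0.3))
  kin <- link_kinematics(mod, st)
  ors <- list(kin$R, kin$R)
  f <- file.path(tmp, "orient.csv")
  write_orientation_csv(ors, c(0, 0.02), paste0("L", 1:5), f)
  back <- read_orientation_csv(f)
  expect_equal(back$time, c(0, 0.02))
  for (i in 1:5)
    expect_equal(back$orientations[[1]][[i]], kin$R[[i]], tolerance = 1e-9)

  jf <- file.path(tmp, "joints.csv")
  S <- matrix(rnorm(8), 2, 4)
  write_joint_csv(c(0, 0.02), S, S * 2, S * 3, path = jf)
  jb <- read_joint_csv(jf)
  expect_equal(jb$s, S, ignore_attr = TRUE)
  expect_equal(jb$s_ddot, S * 3, ignore_attr = TRUE)

  ff <- file.path(tmp, "forces.csv")
  write_forces_csv(c(0, 0.02), c(700, 650), c(0, 50), ff)
  fb <- read_forces_csv(ff)
  expect_equal(fb$rf_fz, c(700, 650))

  cf <- file.path(tmp, "config.json")
  write_map_config(map_config(Sigma_D = 1e-5, sg_window = 11L), cf)
  cb <- read_map_config(cf)
  expect_equal(cb$Sigma_D, 1e-5)
  expect_equal(cb$sg_window, 11L)
})

test_that("joint rates recovered by IK + Savitzky-Golay give accurate torques", {
  # full pipeline without handing the estimator the exact rates: orientation
  # streams -> IK -> SG differentiation -> MAP; slow trajectory keeps the
  # differentiation error small
  mod <- make_biped_model()
  spec <- trajectory_spec(mod,
    joints = data.frame(amp = 0.15, freq = 0.3, phase = c(0, 1, 2, 3),
                        offset = c(0, 0, -0.5, -0.5)),
    base = list(mode = "free", lin_amp = c(0.02, 0, 0.01),
                ang_axis = c(0, 0, 1), ang_amp = 0.1, ang_freq = 0.3),
    duration = 1, rate = 50)
  gt <- simulate_trajectory(spec)
  lay <- sensor_layout(mod, ft_links = c(1L, 4L, 5L))
  streams <- generate_measurements(gt, lay)
  streams$s <- NULL; streams$s_dot <- NULL   # force the kinematics stage
  fit <- estimate_dynamics(mod, streams, layout = lay)
  interior <- 5:(length(gt$time) - 4)
  expect_lt(max(abs(fit$s[interior, ] - t(vapply(gt$states, `[[`,
    numeric(4), "s"))[interior, ])), 1e-6)
  expect_lt(max(abs(fit$tau[interior, ] - gt$tau[interior, ])), 0.5)
})
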