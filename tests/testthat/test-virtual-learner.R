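test_that("trajectory generation is seeded, periodic, and mode-dependent", {
  cfg <- learner_config(seed = 17, duration = 6)
  t1 <- make_trajectory(cfg)
  t2 <- make_trajectory(cfg)
  expect_identical(t1, t2)                 # bit-identical under the same seed

  cfg2 <- learner_config(seed = 18, duration = 6)
  expect_false(identical(make_trajectory(cfg2)$x, t1$x))

  # jitter off: consecutive periods are numerically identical
  cfg0 <- learner_config(seed = 17, duration = 6, amplitude_jitter = 0,
                         phase_jitter = 0)
  tr <- make_trajectory(cfg0)
  expect_equal(tr$x[201:400], tr$x[1:200], tolerance = 1e-9)
  expect_equal(tr$z[201:400], tr$z[1:200], tolerance = 1e-9)

  # the speed minimum at the top of the curve exists only with the pause
  speed_at_top <- function(mode) {
    c0 <- learner_config(seed = 3, duration = 4, class_mode = mode,
                         amplitude_jitter = 0, phase_jitter = 0,
                         noise_density = 0)
    tr <- make_trajectory(c0)
    v <- sqrt(diff(tr$x)^2 + diff(tr$z)^2) * c0$sample_rate
    top <- which(abs(attr(tr, "phase")[-1] - 0.25) < 0.02)
    away <- which(abs(attr(tr, "phase")[-1] - 0.75) < 0.02)
    mean(v[top]) / mean(v[away])
  }
  expect_lt(speed_at_top("alpha"), 0.3)
  expect_gt(speed_at_top("beta"), 0.8)

  expect_error(learner_config(pause = 3, period = 2), class = "mt_config_error")
})

test_that("a static trajectory reads gravity on the sensor z axis", {
  cfg <- learner_config(seed = 1, duration = 1, noise_density = 0,
                        wobble_deg = 0)
  traj <- data.frame(t = (0:99) / 100, x = 0.1, y = 0, z = -0.05)
  st <- synth_stream(traj, cfg)
  expect_equal(unname(st$accel[50, ]), c(0, 0, 9.81), tolerance = 1e-9)
})

test_that("the stream inverts through the preprocessing chain", {
  cfg <- learner_config(seed = 42, duration = 8, noise_density = 0,
                        wobble_deg = 0, amplitude_jitter = 0, phase_jitter = 0)
  traj <- make_trajectory(cfg)
  st <- synth_stream(traj, cfg)

  # unfiltered acceleration recovery is exact up to differencing round-off
  ms <- select_signals(st, data.frame(index = 1L, sensor = "s1", axis = "x",
                                      kind = "accel"),
                       fc = NULL, detrend = FALSE)
  n <- nrow(traj)
  acc_true <- c(NA, diff(diff(traj$x)) * cfg$sample_rate^2, NA)
  expect_lt(max(abs(ms$signals[["1"]]$values[2:(n - 1)] - acc_true[2:(n - 1)])),
            1e-6)

  # and with the sensor wobbling, the quaternion track undoes the rotation
  cfg_w <- learner_config(seed = 42, duration = 8, noise_density = 0,
                          wobble_deg = 8, amplitude_jitter = 0, phase_jitter = 0)
  st_w <- synth_stream(traj, cfg_w)
  ms_w <- select_signals(st_w, data.frame(index = 1L, sensor = "s1", axis = "x",
                                          kind = "accel"),
                         fc = NULL, detrend = FALSE)
  expect_lt(max(abs(ms_w$signals[["1"]]$values[2:(n - 1)] - acc_true[2:(n - 1)])),
            1e-6)

  # double integration reproduces the centred position trajectory
  msp <- select_signals(st, data.frame(index = 1L, sensor = "s1", axis = "x",
                                       kind = "position"),
                        fc = NULL, period_w = 200)
  cut <- 201:750
  rec <- msp$signals[["1"]]$values[cut]
  gen <- traj$x[cut]
  expect_lt(max(abs((rec - mean(rec)) - (gen - mean(gen)))), 0.02)
  expect_gt(cor(rec, gen), 0.999)
})

test_that("accelerometer noise matches the configured density", {
  cfg_n <- learner_config(seed = 5, duration = 10, wobble_deg = 0,
                          amplitude_jitter = 0, phase_jitter = 0)
  cfg_0 <- learner_config(seed = 5, duration = 10, wobble_deg = 0,
                          amplitude_jitter = 0, phase_jitter = 0,
                          noise_density = 0)
  traj <- make_trajectory(cfg_0)
  resid <- synth_stream(traj, cfg_n)$accel - synth_stream(traj, cfg_0)$accel
  sigma_target <- 0.4e-3 * 9.81 * sqrt(100 / 2)
  expect_lt(abs(sd(resid) / sigma_target - 1), 0.2)
})

test_that("training sets are labelled, sized, and preprocessed", {
  cfgs <- list(Calpha = learner_config(class_mode = "alpha", duration = 6),
               Cbeta = learner_config(class_mode = "beta", duration = 6))
  ts <- make_training_set(cfgs, 3, seed = 77)
  expect_length(ts, 6)
  expect_equal(table(vapply(ts, function(r) r$label, character(1))),
               table(rep(c("Calpha", "Cbeta"), each = 3)))
  expect_s3_class(ts[[1]]$msig, "multi_signal")
  expect_s3_class(ts[[1]]$stream, "sensor_stream")
})
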