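test_that("quaternions map to proper rotation matrices", {
  expect_equal(quat_to_rotation(c(0, 0, 0, 1)), diag(3))

  # 90 degrees about z maps x onto y
  A <- quat_to_rotation(c(0, 0, sin(pi / 4), cos(pi / 4)))
  expect_equal(as.numeric(A %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    q <- rnorm(4)
    A <- quat_to_rotation(q)
    expect_lt(max(abs(crossprod(A) - diag(3))), 1e-9)
    expect_lt(abs(det(A) - 1), 1e-9)
  }
  expect_error(quat_to_rotation(c(0, 0, 0, 0)), class = "mt_invalid_input")
})

test_that("sensor-to-inertial conversion applies the inverse rotation", {
  expect_equal(to_inertial(c(1, 2, 3), diag(3)), c(1, 2, 3))

  A <- quat_to_rotation(c(0, 0, sin(pi / 4), cos(pi / 4)))
  expect_equal(to_inertial(c(1, 0, 0), A), c(0, -1, 0), tolerance = 1e-12)

  # frame round trip is the identity
  set.seed(4)
  a <- rnorm(3)
  q <- rnorm(4)
  A <- quat_to_rotation(q)
  expect_equal(as.numeric(A %*% to_inertial(a, A)), a, tolerance = 1e-12)

  expect_error(to_inertial(c(1, 0, 0), matrix(1, 3, 3)), class = "mt_invalid_input")
})

test_that("gravity removal subtracts g0 from the inertial z axis", {
  expect_equal(remove_gravity(c(0, 0, 9.81)), c(0, 0, 0))
  expect_equal(remove_gravity(c(1, 0, 9.81)), c(1, 0, 0))
  m <- remove_gravity(rbind(c(0, 0, 9.81), c(1, 2, 11.81)))
  expect_equal(m, rbind(c(0, 0, 0), c(1, 2, 2)))
})

test_that("IIR low-pass has unit DC gain, the RC alpha, and is linear", {
  s <- one_d_signal(rep(3.2, 100), kind = "accel", axis = "x", index = 1)
  expect_equal(iir_lowpass(s, 5)$values, rep(3.2, 100))

  expect_equal(round(motionteach:::iir_alpha(5, 100), 4), 0.2391)

  set.seed(2)
  x1 <- rnorm(200); x2 <- rnorm(200)
  y12 <- iir_lowpass(x1 + x2, 5, sample_rate = 100)
  expect_equal(y12, iir_lowpass(x1, 5, sample_rate = 100) +
                     iir_lowpass(x2, 5, sample_rate = 100),
               tolerance = 1e-12)

  expect_error(iir_lowpass(x1, 60, sample_rate = 100), class = "mt_invalid_input")
  expect_error(iir_lowpass(x1, 0, sample_rate = 100), class = "mt_invalid_input")
})

test_that("white-noise RMS attenuation at fc = 5 Hz is near 10 dB", {
  set.seed(33)
  x <- rnorm(200000)
  y <- iir_lowpass(x, 5, sample_rate = 100)
  att_db <- -20 * log10(sd(y) / sd(x))
  expect_gt(att_db, 8)
  expect_lt(att_db, 12)
})

test_that("Euler integration matches closed forms and respects detrending", {
  z <- one_d_signal(rep(0, 50), kind = "accel", axis = "x", index = 1)
  expect_equal(integrate_signal(z)$values, rep(0, 50))

  a1 <- one_d_signal(rep(1, 100), kind = "accel", axis = "x", index = 1)
  v <- integrate_signal(a1)
  expect_equal(v$kind, "velocity")
  expect_equal(v$values[100], 1.0, tolerance = 0.01)

  # periodic input with per-period detrend integrates to a periodic output
  tt <- (0:799) / 100
  acc <- one_d_signal(sin(2 * pi * tt / 2), kind = "accel", axis = "x", index = 1)
  vel <- integrate_signal(acc, detrend_per_period = TRUE, period_w = 200)
  per_means <- colMeans(matrix(diff(c(0, vel$values)), nrow = 200))
  expect_lt(max(abs(per_means)), 1e-9)

  pos <- one_d_signal(rep(0, 10), kind = "position", axis = "x", index = 1)
  expect_error(integrate_signal(pos), class = "mt_invalid_kind")
})

test_that("select_signals builds the requested multi-signal", {
  cfg <- learner_config(seed = 9, duration = 6)
  st <- synth_stream(make_trajectory(cfg), cfg)

  one <- select_signals(st, data.frame(index = 7L, sensor = "s1",
                                       axis = "x", kind = "accel"))
  expect_s3_class(one, "multi_signal")
  expect_equal(one$indices, 7L)
  expect_equal(one$signals[["7"]]$kind, "accel")

  # the experiment's shape signals: x and z positions
  two <- select_signals(st, data.frame(index = c(1L, 2L), sensor = "s1",
                                       axis = c("x", "z"), kind = "position"),
                        period_w = 200)
  expect_equal(vapply(two$signals, function(s) s$kind, character(1)),
               c("1" = "position", "2" = "position"))

  expect_error(select_signals(st, data.frame()), class = "mt_config_error")
  expect_error(select_signals(st, data.frame(index = 1L, sensor = "nope",
                                             axis = "x", kind = "accel")),
               class = "mt_config_error")
})
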