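fx_scores <- function() load_efficiency_fixture()

test_that("RMSE against the aligned shape pattern", {
  w <- 100
  P <- pattern1d(sin(2 * pi * (0:(w - 1)) / w), index = 1, roles = "shape")
  m <- 300
  tau <- (((40 - (m - 1)):40 - 1) %% w) + 1    # phase series ending at probe 40
  aligned <- P$probes[tau]
  expect_equal(rmse_signal(aligned, P, tau), 0)

  # deviations of 3 mm and 4 mm over two samples -> sqrt(25/2) mm
  s2 <- aligned
  s2[299:300] <- s2[299:300] + c(0.003, 0.004)
  expect_equal(rmse_signal(s2, P, tau, range = 299:300), sqrt(25 / 2),
               tolerance = 1e-9)

  # uniform offsets increase the error monotonically from zero
  r5 <- rmse_signal(aligned + 0.005, P, tau)
  r10 <- rmse_signal(aligned + 0.010, P, tau)
  expect_lt(0, r5); expect_lt(r5, r10)

  expect_error(rmse_signal(aligned, P, tau, range = integer(0)),
               class = "mt_invalid_input")
})

test_that("E1 averages per-signal RMSEs on the central range", {
  w <- 100
  P1 <- pattern1d(sin(2 * pi * (0:(w - 1)) / w), index = 1, roles = "shape")
  P2 <- pattern1d(cos(2 * pi * (0:(w - 1)) / w), index = 2, roles = "shape")
  m <- 400
  tau <- ((seq_len(m) - 1) %% w) + 1
  s1 <- one_d_signal(P1$probes[tau] + 0.005, kind = "position", axis = "x", index = 1)
  s2 <- one_d_signal(P2$probes[tau] + 0.007, kind = "position", axis = "z", index = 2)
  S <- multi_signal(list(s1, s2))
  r <- e1_score(S, list(P1, P2), tau)
  expect_equal(unname(r$rmse_per_signal), c(5, 7), tolerance = 1e-9)
  expect_equal(r$E1, 6, tolerance = 1e-9)
  expect_equal(r$range, c(120, 360))

  single <- e1_score(multi_signal(list(s1)), list(P1), tau)
  expect_equal(single$E1, unname(single$rmse_per_signal[1]))
})

test_that("E2 starts its window at the longest regulator-class run", {
  w <- 100
  P <- pattern1d(sin(2 * pi * (0:(w - 1)) / w), index = 1, roles = "shape")
  m <- 12000                                # 120 s at 100 Hz
  tau <- ((seq_len(m) - 1) %% w) + 1
  S <- multi_signal(list(one_d_signal(P$probes[tau], kind = "position",
                                      axis = "x", index = 1)))
  all_a <- rep("Calpha", m)
  expect_equal(e2_score(S, list(P), tau, all_a)$window_start, 1L)

  # Cbeta 40 s, Calpha 60 s, Cbeta 20 s -> window starts at t = 40 s
  tl <- c(rep("Cbeta", 4000), rep("Calpha", 6000), rep("Cbeta", 2000))
  r <- e2_score(S, list(P), tau, tl)
  expect_equal(r$window_start, 4001L)
  expect_false(r$truncated)

  # two equal-length runs: the earlier wins
  tl_tie <- c(rep("Calpha", 3000), rep("Cbeta", 1000), rep("Calpha", 3000),
              rep("Cbeta", 5000))
  expect_equal(e2_score(S, list(P), tau, tl_tie)$window_start, 1L)

  # a window overrunning the recording is truncated and flagged
  tl_late <- c(rep("Cbeta", 11000), rep("Calpha", 1000))
  expect_true(e2_score(S, list(P), tau, tl_late)$truncated)

  expect_error(e2_score(S, list(P), tau, rep("Cbeta", m)),
               class = "mt_undefined_e2")
})

test_that("E3 discounts the pre-learning score", {
  expect_equal(e3_score(100, 80), 80)
  expect_equal(e3_score(100, 80, beta = 0), 100)
  # back-solving the discount: E2 = 50 with E3 = 16 implies E2_pre = 136
  expect_equal(e3_score(50, 136), 16)
})

test_that("group statistics reproduce the published summary table", {
  tab <- fx_scores()
  g <- function(p, m) tab$value_mm[tab$parameter == p & tab$method == m]

  expect_equal(group_stats(g("E2", 1))$mean, 69.1, tolerance = 0.3)
  expect_equal(group_stats(g("E1", 2))$mean, 94.5, tolerance = 0.3)
  expect_equal(group_stats(g("E2", 2))$mean, 95.8, tolerance = 0.3)
  expect_equal(group_stats(g("E3", 2))$mean, 70.3, tolerance = 0.3)
  expect_equal(group_stats(g("E1", 1))$sd, 15, tolerance = 0.5)
  expect_equal(group_stats(g("E2", 1))$sd, 21, tolerance = 0.5)
  expect_equal(group_stats(g("E3", 1))$sd, 26, tolerance = 0.5)

  expect_equal(group_stats(c(5, 5, 5, 5)), list(mean = 5, sd = 0))
  expect_error(group_stats(3), class = "mt_invalid_input")
})

test_that("the statistical battery computes one-sided pooled t with critical values", {
  tab <- fx_scores()
  g <- function(p, m) tab$value_mm[tab$parameter == p & tab$method == m]

  b <- test_battery(g("E1", 1), g("E1", 2), sw_draws = 0)
  expect_equal(b$t_crit, 1.746, tolerance = 1e-3)
  expect_equal(b$levene_crit, 4.49, tolerance = 0.01)
  expect_equal(b$df, 16L)
  # recomputed from the rounded published scores (the source article prints
  # 1.75, most likely from unrounded data)
  expect_equal(b$t, 1.85, tolerance = 0.01)
  expect_true(b$p < 0.05)

  # swapping the groups flips the sign of t
  b_swap <- test_battery(g("E1", 2), g("E1", 1), sw_draws = 0)
  expect_equal(b_swap$t, -b$t, tolerance = 1e-12)

  expect_error(test_battery(c(1, 1, 1), c(2, 2, 2), sw_draws = 0),
               class = "mt_test_undefined")
  expect_error(test_battery(c(1, 2), c(1, 2, 3), sw_draws = 0),
               class = "mt_invalid_input")
})

test_that("the full efficiency analysis covers every parameter", {
  rep_ <- efficiency_analysis(fx_scores(), sw_draws = 500, seed = 2)
  expect_setequal(names(rep_), c("E1", "E2", "E3"))
  expect_equal(rep_$E2$t, 1.91, tolerance = 0.01)
  expect_equal(rep_$E3$t, 1.93, tolerance = 0.01)
  expect_true(all(vapply(rep_, function(x) x$p, numeric(1)) < 0.07))
})
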