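test_that("window normalization maps extremes onto the fixed band", {
  r <- normalize_window(c(0, 1))
  expect_equal(r$values, c(-0.6, 0.6))
  expect_equal(r$zeta, 1.2)
  expect_equal(r$eta, -0.6)

  r2 <- normalize_window(c(-0.6, 0.1, 0.6))
  expect_equal(r2$zeta, 1)
  expect_equal(r2$eta, 0)

  set.seed(5)
  x <- rnorm(50)
  rx <- normalize_window(x)
  expect_equal(min(rx$values), -0.6, tolerance = 1e-9)
  expect_equal(max(rx$values), 0.6, tolerance = 1e-9)

  rd <- normalize_window(c(5, 5, 5))
  expect_true(rd$degenerate)
  expect_equal(rd$values, c(0, 0, 0))
  expect_equal(rd$zeta, 0)

  expect_error(normalize_window(3), class = "mt_invalid_input")
})

test_that("the g distance is zero on aligned data and invariant to its transform", {
  P <- c(1, 2, 3)
  expect_equal(g_distance(P, c(9, 9, 1, 2, 3), a = 1, b = 3, c = 1, d = 0, n = 3), 0)
  # value transform absorbed by (c, d)
  expect_equal(g_distance(P, c(9, 9, 3, 5, 7), a = 1, b = 3, c = 2, d = 1, n = 3), 0)
  # hand-computed mismatch: ((3-4)^2 + 0 + 0) / 3
  expect_equal(g_distance(P, c(9, 9, 1, 2, 4), a = 1, b = 3, c = 1, d = 0, n = 3), 1 / 3)

  expect_error(g_distance(P, c(1, 2), a = 1, b = 3, c = 1, d = 0, n = 3),
               class = "mt_invalid_input")
  expect_error(g_distance(P, c(1, 2, 3), a = 1, b = 3, c = 1, d = 0, n = 0),
               class = "mt_invalid_input")
})

test_that("two-stage search recovers on-grid generating parameters exactly", {
  w <- 50
  p <- sin(2 * pi * (0:(w - 1)) / w) + 0.4 * sin(4 * pi * (0:(w - 1)) / w)
  grid <- match_grid(a_range = c(1, 1), a_card = 1,
                     b_range = c(1, w), b_card = w,
                     c_range = c(0.5, 1.5), c_card = 11,
                     d_range = c(-0.5, 0.5), d_card = 11,
                     refine_factor = 5, n_refine_regions = 3)
  # signal = pattern shifted by 7 probes, scaled by 1.2, offset 0.3 (all on-grid)
  k <- 0:(w - 1)
  b_true <- 30
  s <- rev(p[((b_true - k - 1) %% w) + 1] * 1.2 + 0.3)
  r <- h_distance(p, s, grid = grid, n = w, normalize = FALSE)
  expect_equal(r$h, 0, tolerance = 1e-18)
  expect_equal(r$match$b, b_true)
  expect_equal(r$match$c, 1.2)
  expect_equal(r$match$d, 0.3)
})

test_that("the normalized distance is invariant under linear signal transforms", {
  w <- 100
  p <- sin(2 * pi * (0:(w - 1)) / w)
  set.seed(8)
  s <- rep(p, 3) + rnorm(3 * w, sd = 0.05)
  h0 <- h_distance(p, s)$h
  for (tr in list(c(2.5, 0), c(1, -4), c(0.3, 1.7))) {
    ht <- h_distance(p, s * tr[1] + tr[2])$h
    expect_lt(abs(ht - h0), 1e-9)
  }
})

test_that("stage-1 evaluation counts follow the grid cardinalities", {
  g_full <- default_grid(200, full = TRUE)
  expect_identical(g_full$n_stage1, 30L * 20L * 15L * 25L)
  expect_identical(g_full$n_stage1, 225000L)

  p <- sin(2 * pi * (0:199) / 200)
  s <- rep(p, 3)
  r <- h_distance(p, s)          # reduced default grid, normalized
  expect_identical(r$match$n_eval_stage1, default_grid(200)$n_stage1)
  expect_lte(r$match$n_eval_stage1, 10000)
})

test_that("two-stage minimizer never beats nor trails the exhaustive oracle", {
  set.seed(7)
  n_eq <- 0
  for (i in 1:5) {
    w <- 40
    p <- sin(2 * pi * (0:(w - 1)) / w) + 0.3 * cos(4 * pi * (0:(w - 1)) / w) +
      rnorm(w, sd = 0.1)
    s <- rep(p, 3)[1:100] * runif(1, 0.8, 1.2) + rnorm(100, sd = 0.05)
    g <- match_grid(a_range = c(0.8, 1.2), a_card = 5, b_range = c(1, w), b_card = 5,
                    c_range = c(0.9, 1.1), c_card = 5, d_range = c(-0.1, 0.1), d_card = 5,
                    refine_factor = 3, n_refine_regions = 3)
    h2 <- h_distance(p, s, grid = g, n = w)
    ho <- h_oracle(p, s, grid = g, n = w)
    expect_gte(h2$h + 1e-12, ho$h)         # oracle is a superset minimum
    if (abs(h2$h - ho$h) < 1e-12) n_eq <- n_eq + 1
  }
  expect_gte(n_eq, 4)
  # a perfectly matched pair is found exactly by both routes
  w <- 40
  p <- sin(2 * pi * (0:(w - 1)) / w)
  g <- match_grid(a_range = c(1, 1), a_card = 1, b_range = c(1, w), b_card = w,
                  c_range = c(1, 1), c_card = 1, d_range = c(0, 0), d_card = 1,
                  refine_factor = 2)
  expect_equal(h_oracle(p, rep(p, 2), grid = g, n = w, normalize = FALSE)$h, 0)
})
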