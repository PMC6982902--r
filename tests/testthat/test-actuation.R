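test_that("actuator vector algebra: mixing, frame change, projection", {
  C <- rbind(c(1, 0), c(0, 1), c(0, 0))
  expect_equal(actuator_vector(C, c(0.05, -0.02)), c(0.05, -0.02, 0))
  expect_equal(actuator_vector(C, c(0, 0)), c(0, 0, 0))
  set.seed(6)
  e1 <- rnorm(2); e2 <- rnorm(2)
  expect_equal(actuator_vector(C, e1 + e2),
               actuator_vector(C, e1) + actuator_vector(C, e2),
               tolerance = 1e-12)
  expect_error(actuator_vector(C, c(1, 2, 3)), class = "mt_config_error")

  expect_equal(to_actuator_frame(diag(3), c(1, 2, 3)), c(1, 2, 3))
  A <- quat_to_rotation(c(0, 0, sin(pi / 4), cos(pi / 4)))
  expect_equal(to_actuator_frame(A, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  q <- rnorm(4); Ar <- quat_to_rotation(q); v <- rnorm(3)
  expect_equal(sqrt(sum(to_actuator_frame(Ar, v)^2)), sqrt(sum(v^2)),
               tolerance = 1e-12)

  G <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(project_to_plane(G, c(1, 2, 3)), c(1, 3))
  expect_equal(project_to_plane(G, c(0, 5, 0)), c(0, 0))
  th <- 30 * pi / 180
  G_rot <- rbind(c(cos(th), 0, -sin(th)), c(sin(th), 0, cos(th)))
  w_in <- c(0.3, 0, 0.4)                   # in-plane vector
  expect_equal(sqrt(sum(project_to_plane(G_rot, w_in)^2)), 0.5,
               tolerance = 1e-12)
})

test_that("unit selection picks the nearest direction sector", {
  expect_equal(select_unit(c(0.05, 0.01)), 0L)   # 11.3 degrees -> 0-degree unit
  expect_equal(select_unit(c(0, 0.1)), 1L)
  expect_equal(select_unit(c(-1, 0)), 2L)
  expect_equal(select_unit(c(0, -1)), 3L)
  # rotating the vector by 90 degrees advances the unit id by 1 (mod 4)
  o <- c(0.7, 0.2)
  rot90 <- function(v) c(-v[2], v[1])
  u <- select_unit(o)
  for (i in 1:3) {
    o <- rot90(o)
    expect_equal(select_unit(o), (u + i) %% 4L)
  }
  expect_error(select_unit(c(0, 0)), class = "mt_invalid_input")
})

test_that("the regulator algorithm gates on length, spacing and outward crossing", {
  cfg <- actuator_config("a1", C = rbind(c(1, 0), c(0, 0), c(0, 1)))
  mk_state <- function(last = -10) {
    st <- teach_state("a1")
    st$last_activation[["a1"]] <- last
    st
  }
  gate_out <- list(pos = c(0.3, 0), centroid = c(0, 0),
                   vel = c(0.5, 0), e_xz = c(0.04, 0))
  e <- structure(list(e = c(0.04, 0), mapping = c("1", "2")), class = "error_vector")

  # |o| = 0.04 > len, elapsed 10 s > elaps, outward gate true -> one command
  r <- alg_c_alpha(mk_state(), list(cfg), e, NULL, t = 0, period_end = TRUE,
                   gate = gate_out)
  expect_length(r$commands, 1)
  expect_equal(r$commands[[1]]$algorithm, "Calpha")
  expect_equal(r$state$last_activation[["a1"]], 0)
  expect_equal(unname(r$state$o_max["a1"]), 0)   # per-period max reset

  # below the length threshold: silent
  e_small <- structure(list(e = c(0.02, 0), mapping = c("1", "2")),
                       class = "error_vector")
  r2 <- alg_c_alpha(mk_state(), list(cfg), e_small, NULL, t = 0,
                    period_end = TRUE, gate = gate_out)
  expect_length(r2$commands, 0)

  # too soon after the previous activation: silent regardless of |o|
  r3 <- alg_c_alpha(mk_state(last = -1), list(cfg), e, NULL, t = 0,
                    period_end = TRUE, gate = gate_out)
  expect_length(r3$commands, 0)

  # inward-moving body part never triggers
  gate_in <- list(pos = c(0.3, 0), centroid = c(0, 0),
                  vel = c(-0.5, 0), e_xz = c(0.04, 0))
  r4 <- alg_c_alpha(mk_state(), list(cfg), e, NULL, t = 0, period_end = TRUE,
                    gate = gate_in)
  expect_length(r4$commands, 0)

  # no command outside a period end; the running max accumulates instead
  r5 <- alg_c_alpha(mk_state(), list(cfg), e, NULL, t = 0, period_end = FALSE,
                    gate = gate_out)
  expect_length(r5$commands, 0)
  expect_equal(unname(r5$state$o_max["a1"]), 0.04)
})

test_that("the time-triggered algorithm fires once per trigger crossing", {
  w <- 200
  mk_tpe <- function(tau, reliable = TRUE)
    structure(list(tau = tau, w = w, reliable = reliable, h_best = 0.01),
              class = "time_point_estimate")
  cfg <- list(trigger_probe = 120, actuator_id = "a1", unit_id = 2L,
              min_spacing = 0)
  run_sweep <- function(trigger, reliable = TRUE, n_periods = 3) {
    cfg$trigger_probe <- trigger
    st <- teach_state("a1")
    st$prev_tau <- 1
    fired <- 0
    tick <- 0
    for (rep in seq_len(n_periods)) for (tau in seq(2, w, by = 2)) {
      tpe <- mk_tpe(tau, reliable)
      r <- alg_c_beta(st, cfg, tpe, t = tick)
      st <- r$state
      st$prev_tau <- tau
      fired <- fired + length(r$commands)
      tick <- tick + 0.01
    }
    fired
  }
  expect_equal(run_sweep(120), 3)          # exactly one per period
  expect_equal(run_sweep(120, reliable = FALSE), 0)
  expect_equal(run_sweep(200), 3)          # trigger at the wrap boundary
  # a trigger at probe 1 is crossed only when tau wraps between periods
  expect_equal(run_sweep(1), 2)
})

test_that("incoherent time-point jumps are not treated as crossings", {
  w <- 200
  cfg <- list(trigger_probe = 120, actuator_id = "a1", unit_id = 0L,
              min_spacing = 0)
  st <- teach_state("a1")
  st$prev_tau <- 10
  tpe <- structure(list(tau = 150, w = w, reliable = TRUE, h_best = 0.01),
                   class = "time_point_estimate")   # 140-probe jump
  r <- alg_c_beta(st, cfg, tpe, t = 0)
  expect_length(r$commands, 0)
})

test_that("teach_step demands a pattern bank", {
  S <- fx_msig("alpha", seed = 41, duration = 6)
  session <- session_from_bank(fx_bank())
  st <- teach_state("band1")
  expect_error(teach_step(list(), S, st, session, 500), class = "mt_config_error")
})
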