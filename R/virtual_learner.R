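#' Virtual-learner configuration
#'
#' Parameters of the synthetic periodic hand trajectory and its sensor
#' model. The trajectory is a closed ellipse in the x-z plane traversed
#' once per period; in `"alpha"` mode the traversal slows to a near-stop
#' (a timed pause) at the top of the curve, while `"beta"` mode - the
#' typical-error class - removes the pause. Per-period amplitude and
#' timing jitter emulate human repetition variability; the accelerometer
#' adds band-limited white noise of the configured density and the sensor
#' orientation wobbles slowly around its base attitude.
#'
#' @param ax,az ellipse semi-axes, metres.
#' @param period motion period, seconds (default 2).
#' @param pause pause duration, seconds (width of the slow segment).
#' @param pause_phase phase fraction of the pause centre (0.25 = top).
#' @param pause_depth fractional speed reduction inside the pause
#'   (0 = none, 1 = full stop; default 0.92).
#' @param class_mode `"alpha"` (pause present) or `"beta"` (pause absent).
#' @param amplitude_jitter sd of the per-period amplitude factor.
#' @param phase_jitter sd of the per-period timing offset, seconds.
#' @param base_quat base sensor orientation `(vx, vy, vz, k)`.
#' @param wobble_deg amplitude of the slow orientation wobble, degrees.
#' @param wobble_period wobble period, seconds.
#' @param noise_density accelerometer noise density, mg per sqrt(Hz)
#'   (default 0.4).
#' @param sample_rate Hz (default 100).
#' @param duration recording length, seconds.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param sensor_id id given to the generated stream.
#' @return A list of class `learner_config`.
#' @export
learner_config <- function(ax = 0.25, az = 0.15, period = 2, pause = 0.4,
                           pause_phase = 0.25, pause_depth = 0.92,
                           class_mode = c("alpha", "beta"),
                           amplitude_jitter = 0.05, phase_jitter = 0.02,
                           base_quat = c(0, 0, 0, 1), wobble_deg = 5,
                           wobble_period = 10, noise_density = 0.4,
                           sample_rate = 100, duration = 10, seed = NULL,
                           sensor_id = "s1") {
  class_mode <- match.arg(class_mode)
  if (period <= 0) mt_config_error("period must be positive")
  if (pause >= period) mt_config_error("pause must be shorter than the period")
  if (noise_density < 0) mt_config_error("noise_density must be >= 0")
  if (ax <= 0 || az <= 0) mt_config_error("ellipse semi-axes must be positive")
  structure(as.list(environment()), class = "learner_config")
}

# Phase-warp lookup: fraction of the period elapsed (0..1) -> fraction of
# the cycle traversed (0..1). The speed profile dips by `depth` inside a
# raised-cosine well of half-width `hw` centred at `u0`, giving a C1 dwell.
warp_table <- function(u0, hw, depth, n_tab = 2048) {
  u <- seq(0, 1, length.out = n_tab + 1L)
  du <- abs(u - u0)
  du <- pmin(du, 1 - du)                   # cyclic distance
  speed <- 1 - depth * ifelse(du <= hw, 0.5 * (1 + cos(pi * du / hw)), 0)
  W <- cumsum(c(0, (speed[-1] + speed[-length(speed)]) / 2))
  list(u = u, W = W / W[length(W)])
}

#' Generate the virtual learner's hand trajectory
#'
#' Samples the configured closed curve at the sensor rate. The result
#' carries, as attributes, the per-sample true phase (cycle fraction) and
#' the true pattern-probe index, which tests use as ground truth for
#' synchronization.
#'
#' @param cfg a [learner_config()].
#' @return data.frame `t, x, y, z` with attributes `phase` (cycle
#'   fraction in `[0, 1)`) and `true_probe` (probe index in `[1, w]`,
#'   `w = period * sample_rate`).
#' @export
make_trajectory <- function(cfg) {
  n <- round(cfg$duration * cfg$sample_rate)
  tt <- (0:(n - 1)) / cfg$sample_rate
  n_periods <- ceiling(cfg$duration / cfg$period) + 2L
  jit <- with_seed(cfg$seed, list(
    amp = 1 + cfg$amplitude_jitter * stats::rnorm(n_periods),
    off = cfg$phase_jitter * stats::rnorm(n_periods)))
  # per-period jitter values are anchored at period centres and spline-
  # interpolated in time, so the trajectory stays twice differentiable:
  # a piecewise-constant amplitude or timing offset would put position
  # steps at the period boundaries and differentiation would turn them
  # into huge acceleration spikes no real limb produces
  knots <- (seq_len(n_periods) - 0.5) * cfg$period
  amp <- if (cfg$amplitude_jitter > 0)
    stats::spline(knots, jit$amp, xout = tt, method = "natural")$y else rep(1, n)
  off <- if (cfg$phase_jitter > 0)
    stats::spline(knots, jit$off, xout = tt, method = "natural")$y else rep(0, n)
  depth <- if (cfg$class_mode == "alpha") cfg$pause_depth else 0
  hw <- max(cfg$pause / cfg$period, 1e-3)
  # place the speed well so the dwell occurs AT the requested phase: the
  # warp normalization shifts phase ahead of u by half the well area
  u0 <- cfg$pause_phase * (1 - depth * hw) + depth * hw / 2
  tab <- warp_table(u0, hw, depth)
  u_eff <- tt / cfg$period + off / cfg$period
  fu <- u_eff - floor(u_eff)
  phase <- stats::approx(tab$u, tab$W, xout = fu, rule = 2)$y
  phi <- 2 * pi * (floor(u_eff) + phase)
  out <- data.frame(t = tt,
                    x = cfg$ax * amp * cos(phi),
                    y = rep(0, n),
                    z = cfg$az * amp * sin(phi))
  attr(out, "phase") <- phase
  attr(out, "true_probe") <- phase * (cfg$period * cfg$sample_rate) + 1
  out
}

# Hamilton product of quaternions in (vx, vy, vz, k) layout
quat_mult <- function(q1, q2) {
  x1 <- q1[1]; y1 <- q1[2]; z1 <- q1[3]; w1 <- q1[4]
  x2 <- q2[1]; y2 <- q2[2]; z2 <- q2[3]; w2 <- q2[4]
  c(w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2,
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2)
}

quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(axis * sin(angle / 2), cos(angle / 2))
}

#' Synthesize a raw sensor stream from a trajectory
#'
#' Inverts the preprocessing chain: the trajectory is double-differentiated
#' (central differences) to motion acceleration, gravity is added back,
#' and the total inertial acceleration is rotated into the (slowly
#' wobbling) sensor frame by the same rotation convention the
#' preprocessor undoes. Accelerometer noise of the configured density is
#' then added, and the matching quaternion track is emitted.
#'
#' @param traj trajectory from [make_trajectory()].
#' @param cfg the generating [learner_config()].
#' @param g0 gravitational acceleration, m/s^2.
#' @return A [sensor_stream()].
#' @export
synth_stream <- function(traj, cfg, g0 = 9.81) {
  n <- nrow(traj)
  dt <- 1 / cfg$sample_rate
  pos <- as.matrix(traj[, c("x", "y", "z")])
  acc <- matrix(0, n, 3)
  if (n >= 3) {
    acc[2:(n - 1), ] <- (pos[3:n, ] - 2 * pos[2:(n - 1), ] + pos[1:(n - 2), ]) / dt^2
    acc[1, ] <- acc[2, ]; acc[n, ] <- acc[n - 1, ]
  }
  acc[, 3] <- acc[, 3] + g0

  tt <- traj$t
  wob <- cfg$wobble_deg * pi / 180
  th1 <- wob * sin(2 * pi * tt / cfg$wobble_period)
  th2 <- wob * sin(2 * pi * tt / (cfg$wobble_period * 1.37) + 1)
  quats <- matrix(0, n, 4)
  accel <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    q <- quat_mult(cfg$base_quat,
                   quat_mult(quat_axis_angle(c(1, 0, 0), th1[i]),
                             quat_axis_angle(c(0, 1, 0), th2[i])))
    q <- quat_normalize(q)
    quats[i, ] <- q
    A <- quat_to_rotation(q)
    accel[i, ] <- as.numeric(A %*% acc[i, ])  # preprocessor applies t(A)
  }
  if (cfg$noise_density > 0) {
    sigma <- cfg$noise_density * 1e-3 * g0 * sqrt(cfg$sample_rate / 2)
    noise_seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 7919L
    accel <- accel + with_seed(noise_seed,
      matrix(stats::rnorm(n * 3, sd = sigma), n, 3))
  }
  sensor_stream(cfg$sensor_id, accel, quats, cfg$sample_rate)
}

#' Standard signal selection for virtual-learner streams
#'
#' Index 1: x position; index 2: z position (the shape signals); index 3:
#' x acceleration (the synchronization signal).
#'
#' @param sensor_id the stream's sensor id.
#' @return Selection data.frame for [select_signals()].
#' @export
default_selection <- function(sensor_id = "s1") {
  data.frame(index = c(1L, 2L, 3L),
             sensor = sensor_id,
             axis = c("x", "z", "x"),
             kind = c("position", "position", "accel"),
             stringsAsFactors = FALSE)
}

#' Generate a labelled set of recordings for training or benchmarking
#'
#' Produces seeded independent recordings per class, each preprocessed
#' into a [multi_signal()] through [select_signals()].
#'
#' @param configs named list of [learner_config()] objects; names are the
#'   class labels.
#' @param n_recordings recordings per class.
#' @param selection selection data.frame (default [default_selection()]).
#' @param seed master seed; recording `i` of class `j` uses
#'   `seed + 1000 * j + i`.
#' @param fc,detrend passed to [select_signals()].
#' @return List of entries `list(label, stream, msig)`.
#' @export
make_training_set <- function(configs, n_recordings, selection = NULL,
                              seed = 1L, fc = 5, detrend = TRUE) {
  if (!length(configs)) mt_config_error("at least one class config required")
  out <- list()
  for (j in seq_along(configs)) {
    label <- names(configs)[j]
    cfg <- configs[[j]]
    for (i in seq_len(n_recordings)) {
      cfg$seed <- seed + 1000L * j + i
      sel <- if (is.null(selection)) default_selection(cfg$sensor_id) else selection
      stream <- synth_stream(make_trajectory(cfg), cfg)
      msig <- select_signals(stream, sel, fc = fc, detrend = detrend,
                             period_w = round(cfg$period * cfg$sample_rate))
      out[[length(out) + 1L]] <- list(label = label, stream = stream, msig = msig)
    }
  }
  out
}
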