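#' One-dimensional motion signal
#'
#' Container for a uniformly sampled scalar motion signal: one axis of
#' acceleration, velocity or position, in either the sensor-local or the
#' Earth-fixed (inertial) frame. Units follow the kind: m/s^2 for
#' acceleration, m/s for velocity, m for position.
#'
#' @param values numeric vector of samples (at least one).
#' @param kind one of `"accel"`, `"velocity"`, `"position"`.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param index optional integer id used to address the signal inside a
#'   [multi_signal()] selection.
#' @param frame `"sensor"` or `"inertial"`.
#' @param sample_rate sampling rate in Hz (default 100).
#' @return An object of class `one_d_signal`.
#' @export
one_d_signal <- function(values, kind = c("accel", "velocity", "position"),
                         axis = c("x", "y", "z"), index = NULL,
                         frame = c("inertial", "sensor"), sample_rate = 100) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  frame <- match.arg(frame)
  values <- as.numeric(values)
  if (length(values) < 1L) mt_invalid_input("a signal needs at least one sample")
  if (!all(is.finite(values))) mt_invalid_input("signal samples must be finite")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    mt_invalid_input("sample_rate must be positive")
  structure(list(index = index, values = values, kind = kind, axis = axis,
                 frame = frame, sample_rate = sample_rate),
            class = "one_d_signal")
}

#' @export
print.one_d_signal <- function(x, ...) {
  cat(sprintf("<one_d_signal #%s: %s-%s, %d samples @ %g Hz, %s frame>\n",
              if (is.null(x$index)) "?" else x$index, x$kind, x$axis,
              length(x$values), x$sample_rate, x$frame))
  invisible(x)
}

#' @export
length.one_d_signal <- function(x) length(x$values)

#' Multi-dimensional motion signal
#'
#' An indexed set of [one_d_signal()] objects restricted to a selection set
#' of signal indices. All members must share length and sample rate.
#'
#' @param signals list of `one_d_signal` objects; each must carry a
#'   non-`NULL` integer `index`, all distinct.
#' @return An object of class `multi_signal`; members are retrievable by
#'   index via `x$signals[[as.character(i)]]`.
#' @export
multi_signal <- function(signals) {
  if (length(signals) < 1L) mt_invalid_input("selection set must be non-empty")
  idx <- vapply(signals, function(s) {
    if (!inherits(s, "one_d_signal")) mt_invalid_input("all members must be one_d_signal")
    if (is.null(s$index)) mt_invalid_input("every member needs an index")
    as.integer(s$index)
  }, integer(1))
  if (anyDuplicated(idx)) mt_invalid_input("duplicate signal indices")
  lens <- vapply(signals, function(s) length(s$values), integer(1))
  rates <- vapply(signals, function(s) s$sample_rate, numeric(1))
  if (length(unique(lens)) != 1L) mt_invalid_input("member signals must share length")
  if (length(unique(rates)) != 1L) mt_invalid_input("member signals must share sample rate")
  names(signals) <- as.character(idx)
  structure(list(signals = signals, indices = unname(idx),
                 n_samples = lens[[1]], sample_rate = rates[[1]]),
            class = "multi_signal")
}

#' @export
print.multi_signal <- function(x, ...) {
  cat(sprintf("<multi_signal: K = {%s}, %d samples @ %g Hz>\n",
              paste(x$indices, collapse = ","), x$n_samples, x$sample_rate))
  invisible(x)
}

#' Sensor stream: raw accelerometer + orientation samples
#'
#' Per-tick triaxial acceleration in the sensor-local frame together with
#' the orientation quaternion (vector part first, scalar last) describing
#' the sensor's rotation relative to the Earth-fixed frame.
#'
#' @param sensor_id identifier of the sensor.
#' @param accel n x 3 numeric matrix of sensor-frame accelerations (m/s^2).
#' @param quats n x 4 numeric matrix of quaternions `(vx, vy, vz, k)`.
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(sensor_id, accel, quats, sample_rate = 100) {
  accel <- as.matrix(accel); quats <- as.matrix(quats)
  if (ncol(accel) != 3L) mt_invalid_input("accel must have 3 columns")
  if (ncol(quats) != 4L) mt_invalid_input("quats must have 4 columns")
  if (nrow(accel) != nrow(quats))
    mt_invalid_input("accel and quats must have the same number of samples")
  structure(list(sensor_id = sensor_id, accel = accel, quats = quats,
                 sample_rate = sample_rate, n_samples = nrow(accel)),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream '%s': %d samples @ %g Hz>\n",
              x$sensor_id, x$n_samples, x$sample_rate))
  invisible(x)
}

# ---- quaternion / frame algebra -------------------------------------------

quat_normalize <- function(q) {
  q <- as.numeric(q)
  nrm <- sqrt(sum(q^2))
  if (!is.finite(nrm) || nrm == 0) mt_invalid_input("zero-norm quaternion")
  q / nrm
}

#' Rotation matrix from an orientation quaternion
#'
#' Converts a unit quaternion `(vx, vy, vz, k)` (vector part first, scalar
#' last, Hamilton convention) into the 3 x 3 rotation matrix `A` describing
#' the sensor's rotation relative to the Earth-fixed frame. The inverse map
#' (sensor frame to inertial frame) is `t(A)`.
#'
#' @param q numeric length-4 quaternion, vector part first. Normalized
#'   internally; a zero-norm quaternion is an error.
#' @return 3 x 3 orthonormal rotation matrix with determinant +1.
#' @export
quat_to_rotation <- function(q) {
  q <- quat_normalize(q)
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

check_rotation <- function(A, tol = 1e-6) {
  if (!is.matrix(A) || any(dim(A) != c(3L, 3L)))
    mt_invalid_input("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(A) - diag(3))) > tol || abs(det(A) - 1) > tol)
    mt_invalid_input("matrix is not a proper rotation")
  invisible(A)
}

#' Convert a sensor-frame acceleration to the inertial frame
#'
#' Applies `a_iner = B a` with `B = A^-1 = t(A)`, where `A` is the sensor
#' rotation matrix from [quat_to_rotation()].
#'
#' @param a numeric 3-vector, or n x 3 matrix of row vectors.
#' @param A 3 x 3 rotation matrix (validated).
#' @return Same shape as `a`, expressed in the inertial frame.
#' @export
to_inertial <- function(a, A) {
  check_rotation(A)
  if (is.matrix(a)) t(tcrossprod(t(A), a)) else as.numeric(crossprod(A, a))
}

#' Remove gravity from an inertial-frame acceleration
#'
#' Subtracts the constant gravitational acceleration `(0, 0, g0)`; the
#' convention is that a static, upright sensor reads +g0 on the inertial z
#' axis.
#'
#' @param a_iner numeric 3-vector or n x 3 matrix (inertial frame, m/s^2).
#' @param g0 gravitational acceleration, m/s^2.
#' @return Motion acceleration `a_motion`, same shape as the input.
#' @export
remove_gravity <- function(a_iner, g0 = 9.81) {
  if (is.matrix(a_iner)) {
    a_iner[, 3] <- a_iner[, 3] - g0
    a_iner
  } else {
    a_iner - c(0, 0, g0)
  }
}

# Rotate a whole stream's accelerations into the inertial frame (per-tick
# rotation matrices from the quaternion track) and drop gravity.
stream_motion_accel <- function(stream, g0 = 9.81) {
  n <- stream$n_samples
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    A <- quat_to_rotation(stream$quats[i, ])
    out[i, ] <- as.numeric(crossprod(A, stream$accel[i, ]))
  }
  remove_gravity(out, g0)
}

# ---- filtering and integration --------------------------------------------

#' First-order IIR low-pass filter
#'
#' Applies the recurrence `o_k = (1 - alpha) o_{k-1} + alpha f_k` with
#' `alpha = 2 pi fc dt / (2 pi fc dt + 1)` (the standard RC discretization),
#' initialized with the first input sample so there is no start-up step
#' transient. DC gain is exactly 1.
#'
#' @param s a [one_d_signal()] or numeric vector.
#' @param fc cutoff frequency in Hz; must lie in `(0, sample_rate / 2)`.
#' @param sample_rate sampling rate, used when `s` is a bare numeric vector.
#' @return Filtered signal of the same type as the input.
#' @export
iir_lowpass <- function(s, fc, sample_rate = NULL) {
  is_sig <- inherits(s, "one_d_signal")
  rate <- if (is_sig) s$sample_rate else sample_rate
  if (is.null(rate)) mt_invalid_input("sample_rate required for numeric input")
  if (!is.numeric(fc) || fc <= 0 || fc >= rate / 2)
    mt_invalid_input("fc must lie in (0, sample_rate/2)")
  x <- if (is_sig) s$values else as.numeric(s)
  a <- iir_alpha(fc, rate)
  # o_k = (1-a) o_{k-1} + a x_k, o_1 = x_1  ==  filter() with init chosen so
  # the recursion starts at the first sample.
  y <- stats::filter(a * x, 1 - a, method = "recursive", init = x[1])
  y <- as.numeric(y)
  if (is_sig) { s$values <- y; s } else y
}

iir_alpha <- function(fc, sample_rate) {
  x <- 2 * pi * fc / sample_rate
  x / (x + 1)
}

#' Cumulative (Euler) integration of a motion signal
#'
#' Integrates acceleration to velocity, or velocity to position, by the
#' rectangular rule with `dt = 1 / sample_rate`. When `detrend_per_period`
#' is on, the mean of each length-`period_w` window is removed before
#' integration, which keeps the output of a periodic input bounded
#' (per-period drift removal) without modelling sensor drift explicitly.
#'
#' @param s a [one_d_signal()] of kind `"accel"` or `"velocity"`.
#' @param detrend_per_period logical; remove per-window means first.
#' @param period_w window length in samples for the detrending; required
#'   when `detrend_per_period` is `TRUE`. A trailing partial window uses its
#'   own mean.
#' @return A [one_d_signal()] of the next kind (velocity or position).
#' @export
integrate_signal <- function(s, detrend_per_period = FALSE, period_w = NULL) {
  if (!inherits(s, "one_d_signal")) mt_invalid_input("s must be a one_d_signal")
  next_kind <- switch(s$kind, accel = "velocity", velocity = "position",
                      mt_invalid_kind("cannot integrate a position signal"))
  x <- s$values
  if (isTRUE(detrend_per_period)) {
    if (is.null(period_w) || period_w < 1)
      mt_invalid_input("period_w required when detrend_per_period is TRUE")
    x <- detrend_windows(x, as.integer(period_w))
  }
  y <- cumsum(x) / s$sample_rate
  one_d_signal(y, kind = next_kind, axis = s$axis, index = s$index,
               frame = s$frame, sample_rate = s$sample_rate)
}

detrend_windows <- function(x, w) {
  n <- length(x)
  starts <- seq(1L, n, by = w)
  for (st in starts) {
    en <- min(st + w - 1L, n)
    x[st:en] <- x[st:en] - mean(x[st:en])
  }
  x
}

# ---- the preprocessing chain ----------------------------------------------

#' Build a multi-dimensional signal from raw sensor streams
#'
#' Runs the full preprocessing chain for each selected signal index: rotate
#' the sensor-frame acceleration into the inertial frame using the
#' per-sample quaternion, remove gravity, low-pass filter, and integrate
#' once (velocity) or twice (position) as requested. Which signals enter
#' the analysis is an expert/session choice expressed by `selection`.
#'
#' @param streams a [sensor_stream()] or list of them.
#' @param selection data.frame with columns `index` (integer id of the
#'   produced signal), `sensor` (matching a stream's `sensor_id`), `axis`
#'   (`"x"/"y"/"z"`), `kind` (`"accel"/"velocity"/"position"`).
#' @param fc filter cutoff in Hz (default 5, matching a 100 Hz stream);
#'   `NULL` skips the filter entirely.
#' @param detrend logical; per-period mean removal before each integration.
#' @param period_w detrend window, samples. `NULL` estimates it from the
#'   filtered acceleration by autocorrelation; if no period is found the
#'   whole-signal mean is used instead.
#' @param g0 gravitational acceleration (m/s^2).
#' @return A [multi_signal()] whose members carry the requested indices.
#' @export
select_signals <- function(streams, selection, fc = 5, detrend = TRUE,
                           period_w = NULL, g0 = 9.81) {
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  if (!is.data.frame(selection) || nrow(selection) < 1L)
    mt_config_error("selection must be a non-empty data.frame")
  need <- c("index", "sensor", "axis", "kind")
  if (!all(need %in% names(selection)))
    mt_config_error(paste("selection needs columns:", paste(need, collapse = ", ")))
  ids <- vapply(streams, function(s) as.character(s$sensor_id), character(1))
  names(streams) <- ids

  motion_cache <- list()
  sigs <- vector("list", nrow(selection))
  for (r in seq_len(nrow(selection))) {
    sel <- selection[r, ]
    sid <- as.character(sel$sensor)
    if (!sid %in% ids)
      mt_config_error(sprintf("unknown sensor '%s' in selection", sid))
    if (is.null(motion_cache[[sid]]))
      motion_cache[[sid]] <- stream_motion_accel(streams[[sid]], g0)
    axis_i <- match(sel$axis, c("x", "y", "z"))
    if (is.na(axis_i)) mt_config_error(sprintf("unknown axis '%s'", sel$axis))
    if (!sel$kind %in% c("accel", "velocity", "position"))
      mt_config_error(sprintf("unknown kind '%s'", sel$kind))
    rate <- streams[[sid]]$sample_rate
    sig <- one_d_signal(motion_cache[[sid]][, axis_i], kind = "accel",
                        axis = sel$axis, index = sel$index,
                        frame = "inertial", sample_rate = rate)
    if (!is.null(fc)) sig <- iir_lowpass(sig, fc)
    w <- period_w
    if (detrend && is.null(w)) {
      w <- tryCatch(estimate_period(sig$values, sample_rate = rate),
                    motionteach_error = function(e) length(sig$values))
    }
    n_int <- switch(sel$kind, accel = 0L, velocity = 1L, position = 2L)
    for (j in seq_len(n_int))
      sig <- integrate_signal(sig, detrend_per_period = detrend, period_w = w)
    sigs[[r]] <- sig
  }
  multi_signal(sigs)
}
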