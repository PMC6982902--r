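#' Vibrotactile actuator configuration
#'
#' An actuator is a band of directional vibration units on a plane `p`
#' perpendicular to the limb axis. `C` mixes the motion-error vector into
#' the actuator's 3-vector in the inertial frame; the linked sensor's
#' rotation carries it into the actuator frame; `G` projects it onto the
#' actuator plane (and may fold in a mounting-rotation compensation).
#'
#' @param actuator_id identifier.
#' @param C 3 x n weight matrix (n = number of error components).
#' @param G 2 x 3 projection matrix with independent rows.
#' @param linked_sensor id of the sensor whose rotation localizes the
#'   actuator (`NULL` = identity rotation).
#' @param unit_directions angles (degrees) of the vibration units on the
#'   plane; default four units at 0, 90, 180, 270.
#' @return An object of class `actuator_config`.
#' @export
actuator_config <- function(actuator_id, C, G = rbind(c(1, 0, 0), c(0, 0, 1)),
                            linked_sensor = NULL,
                            unit_directions = c(0, 90, 180, 270)) {
  C <- as.matrix(C); G <- as.matrix(G)
  if (nrow(C) != 3L) mt_config_error("C must have 3 rows")
  if (any(dim(G) != c(2L, 3L))) mt_config_error("G must be 2 x 3")
  if (qr(G)$rank < 2L) mt_config_error("G rows must be independent")
  structure(list(actuator_id = actuator_id, C = C, G = G,
                 linked_sensor = linked_sensor,
                 unit_directions = as.numeric(unit_directions),
                 unit_count = length(unit_directions)),
            class = "actuator_config")
}

#' Actuator vector from the motion-error vector
#'
#' `g_i = C e`: a linear combination of error components, in the inertial
#' frame.
#'
#' @param C 3 x n weight matrix.
#' @param e an `error_vector` or numeric vector of length n.
#' @return Numeric 3-vector.
#' @export
actuator_vector <- function(C, e) {
  ev <- if (inherits(e, "error_vector")) e$e else as.numeric(e)
  C <- as.matrix(C)
  if (ncol(C) != length(ev)) mt_config_error("C columns must match the error dimension")
  as.numeric(C %*% ev)
}

#' Express an actuator vector in the actuator's local frame
#'
#' `w_i = A g_i` with `A` the linked sensor's rotation matrix; rotations
#' preserve the vector norm.
#'
#' @param A 3 x 3 rotation matrix.
#' @param g_i numeric 3-vector (inertial frame).
#' @return Numeric 3-vector in the actuator frame.
#' @export
to_actuator_frame <- function(A, g_i) {
  check_rotation(A)
  as.numeric(A %*% g_i)
}

#' Project an actuator vector onto the actuator plane
#'
#' `o_i = G w_i`; the 2 x 3 matrix may also encode an in-plane rotation
#' compensating the mounting orientation.
#'
#' @param G 2 x 3 matrix.
#' @param w_i numeric 3-vector.
#' @return Numeric 2-vector on the plane `p`.
#' @export
project_to_plane <- function(G, w_i) {
  as.numeric(as.matrix(G) %*% w_i)
}

#' Select the vibration unit indicated by a plane vector
#'
#' Returns the unit whose direction angle is nearest (circularly) to the
#' direction of `o_i`; exact boundary ties go to the lower unit id. Unit
#' ids are zero-based.
#'
#' @param o_i numeric 2-vector with positive norm.
#' @param unit_directions unit angles in degrees.
#' @return Integer unit id in `[0, length(unit_directions))`.
#' @export
select_unit <- function(o_i, unit_directions = c(0, 90, 180, 270)) {
  if (sqrt(sum(o_i^2)) == 0) mt_invalid_input("zero vector has no direction")
  ang <- (atan2(o_i[2], o_i[1]) * 180 / pi) %% 360
  d <- abs(((unit_directions - ang + 180) %% 360) - 180)
  which.min(d) - 1L                        # which.min takes the first (lowest id) on ties
}

#' A command emitted to the actuator driver
#'
#' @param actuator_id,unit_id addressed actuator and unit (unit zero-based).
#' @param t emission time, seconds.
#' @param algorithm which teaching algorithm emitted it.
#' @param o_len plane-vector length (m) that triggered a regulator
#'   activation, when applicable.
#' @param pulse pulse metadata; the default is the standard power signal of
#'   two 0.25 s pulses at 20 Hz.
#' @return An object of class `actuator_command`.
#' @export
actuator_command <- function(actuator_id, unit_id, t, algorithm = NA_character_,
                             o_len = NA_real_,
                             pulse = list(count = 2, duration = 0.25, frequency = 20)) {
  structure(list(actuator_id = actuator_id, unit_id = as.integer(unit_id),
                 t = t, algorithm = algorithm, o_len = o_len, pulse = pulse),
            class = "actuator_command")
}

#' @export
print.actuator_command <- function(x, ...) {
  cat(sprintf("<command @ %.2fs: actuator %s unit %d (%s)>\n",
              x$t, x$actuator_id, x$unit_id,
              if (is.na(x$algorithm)) "?" else x$algorithm))
  invisible(x)
}

#' Mutable state of the teaching loop
#'
#' @param actuator_ids ids of the configured actuators.
#' @param len activation threshold on the actuator-plane vector length,
#'   metres (default 0.03).
#' @param elaps minimal spacing between activations of an actuator,
#'   seconds (default 2.5).
#' @return An object of class `teach_state`.
#' @export
teach_state <- function(actuator_ids, len = 0.03, elaps = 2.5) {
  if (len <= 0 || elaps <= 0) mt_invalid_input("len and elaps must be positive")
  ids <- as.character(actuator_ids)
  structure(list(
    len = len, elaps = elaps,
    last_activation = stats::setNames(rep(-Inf, length(ids)), ids),
    o_max = stats::setNames(rep(0, length(ids)), ids),
    o_max_vec = stats::setNames(rep(list(c(0, 0)), length(ids)), ids),
    tau = NA_real_, prev_tau = NA_real_, reliable = FALSE, h_best = Inf,
    label = NA_character_, pending_label = NA_character_, pending_count = 0L),
    class = "teach_state")
}

#' Discrete-regulator teaching algorithm (class of small trajectory errors)
#'
#' Each tick, the plane vectors `o_i` of all actuators are computed and the
#' per-period running maximum of their lengths tracked. At a period end the
#' actuator with the longest recorded vector is the candidate; its unit is
#' fired only if (i) the recorded length exceeds `len`, (ii) at least
#' `elaps` seconds passed since that actuator's previous activation, and
#' (iii) the body part is crossing the taught closed trajectory outward:
#' the error and velocity components along the centroid-to-position
#' direction are both positive.
#'
#' @param state a [teach_state()] (returned updated).
#' @param configs list of [actuator_config()].
#' @param e an `error_vector` from [motion_error()].
#' @param rotations named list (by actuator id) of current 3 x 3 sensor
#'   rotation matrices; missing entries use the identity.
#' @param t current time, seconds.
#' @param period_end logical; `TRUE` on the tick that closes a period.
#' @param gate list with `pos`, `centroid`, `vel`, `e_xz` (2-vectors on the
#'   trajectory plane) used by the outward-crossing detector; `NULL`
#'   disables the gate.
#' @return List `(state, commands)`.
#' @export
alg_c_alpha <- function(state, configs, e, rotations = NULL, t, period_end,
                        gate = NULL) {
  for (cfg in configs) {
    id <- as.character(cfg$actuator_id)
    A <- if (!is.null(rotations) && !is.null(rotations[[id]])) rotations[[id]] else diag(3)
    o <- project_to_plane(cfg$G, A %*% actuator_vector(cfg$C, e))
    len_o <- sqrt(sum(o^2))
    if (len_o > state$o_max[[id]]) {
      state$o_max[[id]] <- len_o
      state$o_max_vec[[id]] <- o
    }
  }
  commands <- list()
  if (period_end) {
    id <- names(state$o_max)[which.max(state$o_max)]
    o_act <- state$o_max_vec[[id]]
    len_act <- state$o_max[[id]]
    gate_ok <- TRUE
    if (!is.null(gate)) {
      radial <- gate$pos - gate$centroid
      nr <- sqrt(sum(radial^2))
      gate_ok <- nr > 0 &&
        sum(gate$e_xz * radial) / nr > 0 &&
        sum(gate$vel * radial) / nr > 0
    }
    if (len_act > state$len &&
        (t - state$last_activation[[id]]) > state$elaps &&
        gate_ok) {
      cfg <- configs[[match(id, vapply(configs, function(x) as.character(x$actuator_id), character(1)))]]
      unit <- select_unit(o_act, cfg$unit_directions)
      commands <- list(actuator_command(id, unit, t, algorithm = "Calpha",
                                        o_len = len_act))
      state$last_activation[[id]] <- t
    }
    state$o_max[] <- 0
    state$o_max_vec <- lapply(state$o_max_vec, function(x) c(0, 0))
  }
  list(state = state, commands = commands)
}

#' Time-triggered teaching algorithm (class of typical motion errors)
#'
#' Fires a teacher-chosen actuator unit when the time point crosses a
#' configured pattern probe (cyclically), provided the synchronization is
#' reliable this tick. Activation may be rate-limited by `min_spacing`.
#'
#' @param state a [teach_state()]; its `prev_tau`/`tau` fields define the
#'   crossing interval (set by the dispatcher).
#' @param config list with `trigger_probe`, `actuator_id`, `unit_id`, and
#'   optional `min_spacing` (seconds, default 0) and `max_delta` (largest
#'   per-tick time-point advance, in probes, accepted as a genuine
#'   crossing; default `w / 8`).
#' @param tpe the current [aggregate_time_point()] estimate.
#' @param t current time, seconds.
#' @return List `(state, commands)`.
#' @export
alg_c_beta <- function(state, config, tpe, t) {
  commands <- list()
  spacing <- if (is.null(config$min_spacing)) 0 else config$min_spacing
  if (tpe$reliable && !is.na(state$prev_tau)) {
    w <- tpe$w
    max_delta <- if (is.null(config$max_delta)) ceiling(w / 8) else config$max_delta
    delta <- (tpe$tau - state$prev_tau) %% w
    to_trig <- (config$trigger_probe - state$prev_tau) %% w
    # an implausibly large advance means the time point was re-acquired,
    # not that the motion passed the trigger; such ticks never fire
    crossed <- delta > 0 && delta <= max_delta && to_trig > 0 && to_trig <= delta
    id <- as.character(config$actuator_id)
    last <- if (id %in% names(state$last_activation)) state$last_activation[[id]] else -Inf
    if (crossed && (t - last) >= spacing) {
      commands <- list(actuator_command(id, config$unit_id, t, algorithm = "Cbeta"))
      state$last_activation[[id]] <- t
    }
  }
  list(state = state, commands = commands)
}

# multi_signal restricted to the samples (t_idx - len + 1) .. t_idx
msig_prefix <- function(msig, t_idx, len) {
  from <- max(1L, t_idx - len + 1L)
  sigs <- lapply(msig$signals, function(s) {
    s$values <- s$values[from:t_idx]
    s
  })
  multi_signal(sigs)
}

#' One tick of the adaptive teaching loop
#'
#' Performs the per-tick sequence: phase synchronization from the time
#' patterns (a full matching solve every `sync_every` ticks, nominal
#' 1-probe-per-tick advance in between), period-end detection by time-point
#' wrap, one classification per period with a 2-decision hysteresis on
#' algorithm switching, motion-error computation, and dispatch to
#' [alg_c_alpha()] (label `"Calpha"`) or [alg_c_beta()] (label `"Cbeta"`).
#' Ticks without reliable synchronization dispatch nothing and report a
#' `"hold"`.
#'
#' @param bank a [pattern_bank()] with class patterns.
#' @param S_cur the preprocessed [multi_signal()] (full recording; the
#'   prefix up to `t_idx` is what the step may use).
#' @param state a [teach_state()].
#' @param session session configuration from [teach_session_config()].
#' @param t_idx current tick (sample index into `S_cur`).
#' @return List with `state`, `decision` (active label or `"hold"`),
#'   `tpe`, `commands`, `period_end`, `classified` (the raw
#'   `class_decision` when one was made this tick).
#' @export
teach_step <- function(bank, S_cur, state, session, t_idx) {
  if (!inherits(bank, "pattern_bank")) mt_config_error("bank must be a pattern_bank")
  w <- session$w
  rate <- S_cur$sample_rate
  t <- (t_idx - 1) / rate

  # --- synchronization -------------------------------------------------
  # per-class time patterns when configured: each class's own templates
  # define its phase origin, so synchronization stays coherent after an
  # algorithm switch
  tps <- session$time_patterns
  if (!inherits(tps[[1]], "pattern1d")) {
    tps <- if (!is.na(state$label) && state$label %in% names(session$time_patterns))
      session$time_patterns[[state$label]]
    else session$time_patterns[[1]]
  }
  full_solve <- is.na(state$tau) || (t_idx %% session$sync_every == 0L)
  if (full_solve) {
    win <- msig_prefix(S_cur, t_idx, session$sync_window)
    cands <- lapply(tps, function(P)
      time_point_1d(P, win$signals[[as.character(P$index)]],
                    grid = session$sync_grid))
    tpe <- aggregate_time_point(cands, w = w, n_best = session$n_best,
                                h_max = session$h_max)
  } else {
    tau <- (state$tau %% w) + 1            # nominal advance: one probe per tick
    tpe <- structure(list(tau = tau, w = w, reliable = state$reliable,
                          h_best = state$h_best, candidates = NULL),
                     class = "time_point_estimate")
  }
  state$prev_tau <- state$tau
  period_end <- !is.na(state$prev_tau) && (tpe$tau < state$prev_tau - w / 2)
  state$tau <- tpe$tau
  state$reliable <- tpe$reliable
  state$h_best <- tpe$h_best

  # --- classification once per period, with switching hysteresis -------
  classified <- NULL
  if (period_end) {
    win <- msig_prefix(S_cur, t_idx, session$class_window)
    classified <- classify_knn(bank, win, k = session$k, grid = session$grid)
    if (identical(classified$label, state$pending_label)) {
      state$pending_count <- state$pending_count + 1L
    } else {
      state$pending_label <- classified$label
      state$pending_count <- 1L
    }
    if (is.na(state$label) || state$pending_count >= session$hysteresis)
      state$label <- state$pending_label
  }

  # --- error computation and algorithm dispatch -------------------------
  commands <- list()
  decision <- "hold"
  if (tpe$reliable && !is.na(state$label)) {
    decision <- state$label
    e <- motion_error(session$shape_patterns, msig_prefix(S_cur, t_idx, session$n_avg + 1L),
                      tpe, n_avg = session$n_avg)
    if (identical(state$label, "Calpha")) {
      gate <- session_gate_info(session, S_cur, t_idx, e)
      rot <- session_rotations(session, t_idx)
      r <- alg_c_alpha(state, session$actuators, e, rot, t, period_end, gate)
      state <- r$state; commands <- r$commands
    } else if (identical(state$label, "Cbeta") && !is.null(session$cbeta)) {
      # crossing interval is (prev_tau, tau]
      r <- alg_c_beta(state, session$cbeta, tpe, t)
      state <- r$state; commands <- r$commands
      if (period_end) {                     # keep the per-period max bookkeeping tidy
        state$o_max[] <- 0
        state$o_max_vec <- lapply(state$o_max_vec, function(x) c(0, 0))
      }
    }
  }
  list(state = state, decision = decision, tpe = tpe, commands = commands,
       period_end = period_end, classified = classified)
}

session_gate_info <- function(session, S_cur, t_idx, e) {
  si <- session$gate_indices
  if (is.null(si) || length(si) != 2L) return(NULL)
  ids <- as.character(si)
  pos <- vapply(ids, function(i) S_cur$signals[[i]]$values[t_idx], numeric(1))
  prev <- vapply(ids, function(i) S_cur$signals[[i]]$values[max(1L, t_idx - 1L)], numeric(1))
  vel <- (pos - prev) * S_cur$sample_rate
  centroid <- vapply(ids, function(i) {
    P <- Filter(function(p) as.character(p$index) == i, session$shape_patterns)
    if (length(P)) mean(P[[1]]$probes) else 0
  }, numeric(1))
  list(pos = pos, centroid = centroid, vel = vel, e_xz = e$e[ids])
}

session_rotations <- function(session, t_idx) {
  if (is.null(session$rotation_tracks)) return(NULL)
  lapply(session$rotation_tracks, function(q) quat_to_rotation(q[t_idx, ]))
}

#' Session configuration for the teaching loop
#'
#' Bundles every tunable of the per-tick loop. Only `w`, `time_patterns`
#' and `shape_patterns` are mandatory; the rest defaults to the values
#' discussed in the package vignette.
#'
#' @param w pattern period, samples.
#' @param time_patterns list of [pattern1d()] used for synchronization, or
#'   a named list (by class label) of such lists for per-class
#'   synchronization templates.
#' @param shape_patterns list of [pattern1d()] used as error references.
#' @param actuators list of [actuator_config()].
#' @param cbeta `NULL` or list(`trigger_probe`, `actuator_id`, `unit_id`,
#'   `min_spacing`).
#' @param k,h_max,n_best,n_avg classifier and synchronization tunables.
#' @param grid,sync_grid matching grids (defaults: [default_grid()],
#'   [sync_grid()]).
#' @param len,elaps activation gating thresholds (m, s).
#' @param sync_every full synchronization solve cadence, ticks.
#' @param hysteresis consecutive agreeing per-period decisions required to
#'   switch the active algorithm.
#' @param sync_window,class_window trailing window lengths (samples) handed
#'   to the synchronization and classification solvers.
#' @param gate_indices length-2 signal indices (x, z position) used by the
#'   outward-crossing gate; `NULL` disables the gate.
#' @param rotation_tracks named list (by actuator id) of per-tick
#'   quaternion matrices for actuator localization; `NULL` = identity.
#' @return A list of class `teach_session_config`.
#' @export
teach_session_config <- function(w, time_patterns, shape_patterns,
                                 actuators = list(), cbeta = NULL,
                                 k = 3, h_max = 0.05, n_best = 3, n_avg = 10,
                                 grid = NULL, sync_grid_ = NULL,
                                 len = 0.03, elaps = 2.5,
                                 sync_every = 5L, hysteresis = 2L,
                                 sync_window = NULL, class_window = NULL,
                                 gate_indices = NULL, rotation_tracks = NULL) {
  if (is.null(grid)) grid <- default_grid(w)
  if (is.null(sync_grid_)) sync_grid_ <- sync_grid(w)
  if (is.null(sync_window)) sync_window <- 3L * w
  if (is.null(class_window)) class_window <- 2L * w
  structure(list(w = as.integer(w), time_patterns = time_patterns,
                 shape_patterns = shape_patterns, actuators = actuators,
                 cbeta = cbeta, k = k, h_max = h_max, n_best = n_best,
                 n_avg = n_avg, grid = grid, sync_grid = sync_grid_,
                 len = len, elaps = elaps, sync_every = as.integer(sync_every),
                 hysteresis = as.integer(hysteresis),
                 sync_window = sync_window, class_window = class_window,
                 gate_indices = gate_indices, rotation_tracks = rotation_tracks),
            class = "teach_session_config")
}

#' Run the teaching loop over a whole recording
#'
#' Iterates [teach_step()] from the end of a warm-up interval to the end of
#' the preprocessed recording and collects the per-tick log, the emitted
#' commands, and the per-period classification decisions.
#'
#' @param S a [multi_signal()] (already preprocessed).
#' @param bank a [pattern_bank()].
#' @param session a [teach_session_config()].
#' @param warmup samples skipped before the loop engages (default `3 * w`).
#' @return List of class `teach_session`: `log` (data.frame `t, tau,
#'   h_best, reliable, label, period_end, n_commands`), `commands` (list of
#'   [actuator_command()]), `decisions` (data.frame of raw per-period
#'   classifications), `state` (final).
#' @export
run_teach_session <- function(S, bank, session, warmup = NULL) {
  if (!inherits(S, "multi_signal")) mt_invalid_input("S must be a multi_signal")
  if (is.null(warmup)) warmup <- 3L * session$w
  n <- S$n_samples
  if (warmup >= n) mt_invalid_input("recording shorter than the warm-up interval")
  ids <- vapply(session$actuators, function(a) as.character(a$actuator_id), character(1))
  if (!is.null(session$cbeta)) ids <- unique(c(ids, as.character(session$cbeta$actuator_id)))
  if (!length(ids)) ids <- "none"
  state <- teach_state(ids, len = session$len, elaps = session$elaps)

  ticks <- seq.int(warmup, n)
  log_rows <- vector("list", length(ticks))
  commands <- list()
  decisions <- list()
  for (j in seq_along(ticks)) {
    t_idx <- ticks[j]
    r <- teach_step(bank, S, state, session, t_idx)
    state <- r$state
    if (length(r$commands)) commands <- c(commands, r$commands)
    if (!is.null(r$classified))
      decisions[[length(decisions) + 1L]] <-
        data.frame(t = (t_idx - 1) / S$sample_rate, label = r$classified$label,
                   min_dist = min(r$classified$dists))
    log_rows[[j]] <- data.frame(
      t = (t_idx - 1) / S$sample_rate, tau = r$tpe$tau, h_best = r$tpe$h_best,
      reliable = r$tpe$reliable, label = r$decision,
      period_end = r$period_end, n_commands = length(r$commands))
  }
  structure(list(log = do.call(rbind, log_rows),
                 commands = commands,
                 decisions = if (length(decisions)) do.call(rbind, decisions) else NULL,
                 state = state, sample_rate = S$sample_rate),
            class = "teach_session")
}

#' @export
print.teach_session <- function(x, ...) {
  cat(sprintf("<teach_session: %d ticks, %d commands, labels: %s>\n",
              nrow(x$log), length(x$commands),
              paste(unique(x$log$label), collapse = ",")))
  invisible(x)
}
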