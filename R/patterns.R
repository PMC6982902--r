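#' One-period motion pattern
#'
#' A template covering exactly one period of a periodic motion signal.
#' Patterns serve three (non-exclusive) roles: `class` templates feed the
#' kNNModel classifier, `time` templates drive phase synchronization, and
#' `shape` templates are the reference for motion-error computation. Role
#' assignment is an expert/session decision, not inferred.
#'
#' @param probes numeric vector of probe values, length `w >= 2`.
#' @param index optional signal index the pattern was built from.
#' @param roles character subset of `c("class", "time", "shape")`.
#' @param units free-text unit label inherited from the source signal.
#' @return An object of class `pattern1d`.
#' @export
pattern1d <- function(probes, index = NULL, roles = character(), units = NULL) {
  probes <- as.numeric(probes)
  if (length(probes) < 2L) mt_invalid_input("a pattern needs w >= 2 probes")
  if (!all(is.finite(probes))) mt_invalid_input("pattern probes must be finite")
  bad <- setdiff(roles, c("class", "time", "shape"))
  if (length(bad)) mt_invalid_input(paste("unknown roles:", paste(bad, collapse = ",")))
  structure(list(index = index, probes = probes, w = length(probes),
                 roles = roles, units = units),
            class = "pattern1d")
}

#' @export
print.pattern1d <- function(x, ...) {
  cat(sprintf("<pattern1d #%s: w = %d probes%s>\n",
              if (is.null(x$index)) "?" else x$index, x$w,
              if (length(x$roles)) paste0(", roles: ", paste(x$roles, collapse = "+")) else ""))
  invisible(x)
}

#' Multi-dimensional pattern
#'
#' A set of one-dimensional patterns indexed by signal id, optionally
#' carrying a class label once banked.
#'
#' @param members list of [pattern1d()] objects with distinct indices.
#' @param label optional class label.
#' @return An object of class `pattern_md`.
#' @export
pattern_md <- function(members, label = NULL) {
  if (length(members) < 1L) mt_invalid_input("pattern_md must be non-empty")
  idx <- vapply(members, function(p) {
    if (!inherits(p, "pattern1d")) mt_invalid_input("members must be pattern1d")
    if (is.null(p$index)) mt_invalid_input("every member pattern needs an index")
    as.integer(p$index)
  }, integer(1))
  if (anyDuplicated(idx)) mt_invalid_input("duplicate member indices")
  names(members) <- as.character(idx)
  structure(list(members = members, indices = unname(idx), label = label),
            class = "pattern_md")
}

#' Labelled pattern bank
#'
#' The ordered sequence of (multi-dimensional pattern, class label) pairs
#' the classifier votes over.
#'
#' @param entries list of [pattern_md()] objects, each with a non-`NULL`
#'   label.
#' @param label_set declared label universe; defaults to the labels present.
#' @return An object of class `pattern_bank`.
#' @export
pattern_bank <- function(entries, label_set = NULL) {
  if (length(entries) < 1L) mt_config_error("pattern bank must hold at least one entry")
  labels <- vapply(entries, function(e) {
    if (!inherits(e, "pattern_md")) mt_invalid_input("entries must be pattern_md")
    if (is.null(e$label)) mt_invalid_input("banked patterns must be labelled")
    as.character(e$label)
  }, character(1))
  if (is.null(label_set)) label_set <- unique(labels)
  if (!all(labels %in% label_set)) mt_invalid_input("label outside declared label_set")
  structure(list(entries = entries, labels = labels,
                 label_set = label_set, n_pairs = length(entries)),
            class = "pattern_bank")
}

#' @export
print.pattern_bank <- function(x, ...) {
  cat(sprintf("<pattern_bank: %d entries, labels {%s}>\n",
              x$n_pairs, paste(x$label_set, collapse = ",")))
  invisible(x)
}

# ---- segmentation ----------------------------------------------------------

#' Estimate the motion period by autocorrelation
#'
#' The period is the lag of the highest autocorrelation peak inside a lag
#' band (default 0.5 s to 4 s). A peak below `threshold` means the signal
#' is not usefully periodic and a segmentation error is raised.
#'
#' @param values numeric samples.
#' @param sample_rate Hz.
#' @param lag_band numeric `(min, max)` lag in samples; default
#'   `c(0.5, 4) * sample_rate`, clipped to half the signal length.
#' @param threshold minimal normalized autocorrelation of the peak.
#' @return Period `w` in samples.
#' @export
estimate_period <- function(values, sample_rate = 100, lag_band = NULL,
                            threshold = 0.3) {
  n <- length(values)
  if (is.null(lag_band)) lag_band <- c(0.5, 4) * sample_rate
  lag_max <- min(floor(lag_band[2]), floor((n - 1) / 2))
  lag_min <- max(2L, ceiling(lag_band[1]))
  if (lag_max <= lag_min)
    mt_segment_error("signal too short for the configured lag band")
  ac <- stats::acf(values, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lag_vals <- ac[(lag_min + 1L):(lag_max + 1L)]       # acf[1] is lag 0
  lags <- lag_min:lag_max
  # local maxima only, so a slowly decaying acf tail does not pass
  is_peak <- c(FALSE, diff(lag_vals) > 0) & c(diff(lag_vals) < 0, FALSE)
  is_peak <- is_peak | seq_along(lag_vals) == which.max(lag_vals)
  cand <- which(is_peak & lag_vals >= threshold)
  if (!length(cand) || max(lag_vals[cand]) < threshold)
    mt_segment_error("no autocorrelation peak above threshold; cannot segment")
  lags[cand[which.max(lag_vals[cand])]]
}

#' Segment a periodic signal into aligned one-period windows
#'
#' Estimates the period with [estimate_period()] (unless `w` is forced),
#' cuts consecutive windows of length `w`, and aligns each window to the
#' first by the cyclic shift maximizing their cross-correlation.
#'
#' @param s a [one_d_signal()] or numeric vector.
#' @param sample_rate Hz, used for numeric input.
#' @param w force a period instead of estimating it.
#' @param lag_band,threshold passed to [estimate_period()].
#' @return List with `w` and `windows` (a list of length-`w` numeric
#'   vectors, cyclically aligned to the first).
#' @export
segment_periods <- function(s, sample_rate = NULL, w = NULL,
                            lag_band = NULL, threshold = 0.3) {
  x <- signal_values(s)
  rate <- if (inherits(s, "one_d_signal")) s$sample_rate else sample_rate
  if (is.null(rate)) rate <- 100
  if (is.null(w)) w <- estimate_period(x, rate, lag_band, threshold)
  w <- as.integer(w)
  n_win <- floor(length(x) / w)
  if (n_win < 1L) mt_segment_error("signal shorter than one period")
  windows <- lapply(seq_len(n_win), function(j) x[((j - 1L) * w + 1L):(j * w)])
  ref <- windows[[1]]
  windows <- lapply(windows, function(win) {
    sh <- best_cyclic_shift(ref, win)
    if (sh == 0L) win else c(win[(sh + 1L):w], win[1:sh])
  })
  list(w = w, windows = windows)
}

# shift (0..w-1) such that rotating `win` left by it best matches `ref`
best_cyclic_shift <- function(ref, win) {
  w <- length(ref)
  xc <- vapply(0:(w - 1L), function(sh) {
    rot <- if (sh == 0L) win else c(win[(sh + 1L):w], win[1:sh])
    sum(ref * rot)
  }, numeric(1))
  which.max(xc) - 1L
}

# ---- pattern construction --------------------------------------------------

# distance used to rank windows during rejection: the matching distance on
# an aligned grid (windows are already phase-aligned, so the time scale is
# pinned at 1 and the shift at w; only small value transforms are searched)
aligned_window_h <- function(pattern_probes, window) {
  w <- length(pattern_probes)
  g <- match_grid(a_range = c(1, 1), a_card = 1,
                  b_range = c(w, w), b_card = 1,
                  c_range = c(0.9, 1.1), c_card = 3,
                  d_range = c(-0.05, 0.05), d_card = 3,
                  refine_factor = 3, n_refine_regions = 1)
  h_distance(pattern_probes, window, grid = g, n = w, normalize = FALSE)$h
}

#' Build a one-period pattern from aligned windows
#'
#' Iterative trimmed averaging, equivalent to a one-cluster k-means under
#' the matching distance: the first round takes the probe-wise mean of all
#' windows; each later round drops the `ceiling(reject_frac * count)`
#' windows farthest (largest aligned matching distance) from the current
#' mean and re-averages the survivors.
#'
#' @param windows list of equal-length numeric vectors (>= 3).
#' @param reject_frac fraction of windows dropped per rejection round, in
#'   `[0, 0.5)`. Zero reduces the procedure to a plain mean.
#' @param n_rounds total rounds including the initial mean (default 2, i.e.
#'   one rejection pass).
#' @param index,roles,units passed to [pattern1d()].
#' @return A [pattern1d()].
#' @export
build_pattern <- function(windows, reject_frac = 0.25, n_rounds = 2,
                          index = NULL, roles = character(), units = NULL) {
  if (length(windows) < 3L) mt_invalid_input("need at least 3 windows")
  if (reject_frac < 0 || reject_frac >= 0.5)
    mt_invalid_input("reject_frac must lie in [0, 0.5)")
  lens <- lengths(windows)
  if (length(unique(lens)) != 1L) mt_invalid_input("windows must share length")
  keep <- windows
  center <- Reduce(`+`, keep) / length(keep)
  if (reject_frac > 0 && n_rounds > 1) {
    for (round in seq_len(n_rounds - 1L)) {
      d <- vapply(keep, function(win) aligned_window_h(center, win), numeric(1))
      n_drop <- ceiling(reject_frac * length(keep))
      if (n_drop >= length(keep)) mt_degenerate("all windows rejected")
      keep <- keep[order(d)[seq_len(length(keep) - n_drop)]]
      center <- Reduce(`+`, keep) / length(keep)
    }
  }
  pattern1d(center, index = index, roles = roles, units = units)
}

#' Build a multi-dimensional pattern from a multi-signal recording
#'
#' Estimates the period of every member signal, requires the estimates to
#' agree within a tolerance (default 5% around the median), then segments
#' each member at the common (median) period and builds one [pattern1d()]
#' per member with [build_pattern()].
#'
#' @param S a [multi_signal()] of recorded periodic motion.
#' @param roles roles attached to every member pattern (or a named list,
#'   by signal index, of per-member role vectors).
#' @param label optional class label for the resulting [pattern_md()].
#' @param reject_frac,n_rounds passed to [build_pattern()].
#' @param w_tol allowed relative spread of per-member period estimates.
#' @param w force a common period, skipping estimation.
#' @return A [pattern_md()].
#' @export
build_pattern_md <- function(S, roles = character(), label = NULL,
                             reject_frac = 0.25, n_rounds = 2,
                             w_tol = 0.05, w = NULL) {
  if (!inherits(S, "multi_signal")) mt_invalid_input("S must be a multi_signal")
  if (is.null(w)) {
    ws <- vapply(S$signals, function(sig)
      estimate_period(sig$values, sig$sample_rate), numeric(1))
    w_med <- stats::median(ws)
    if (any(abs(ws - w_med) / w_med > w_tol))
      mt_segment_error(sprintf(
        "inconsistent periods across signals: %s (median %g)",
        paste(ws, collapse = ","), w_med))
    w <- as.integer(round(w_med))
  }
  members <- lapply(S$signals, function(sig) {
    seg <- segment_periods(sig, w = w)
    r <- if (is.list(roles)) roles[[as.character(sig$index)]] else roles
    build_pattern(seg$windows, reject_frac = reject_frac, n_rounds = n_rounds,
                  index = sig$index, roles = if (is.null(r)) character() else r,
                  units = sig$kind)
  })
  pattern_md(members, label = label)
}

#' Edit a pattern: value transform and resampling
#'
#' Supports expert adjustment of a template to a learner's build: probes
#' are mapped `p -> p * value_scale + value_offset`, then linearly
#' resampled to `resample_w` probes.
#'
#' @param P a [pattern1d()].
#' @param value_scale multiplicative amplitude factor (non-zero).
#' @param value_offset additive offset, pattern units.
#' @param resample_w new period in probes (>= 2); `NULL` keeps the period.
#' @return The edited [pattern1d()].
#' @export
edit_pattern <- function(P, value_scale = 1, value_offset = 0, resample_w = NULL) {
  if (!inherits(P, "pattern1d")) mt_invalid_input("P must be a pattern1d")
  if (value_scale == 0) mt_invalid_input("value_scale must be non-zero")
  probes <- P$probes * value_scale + value_offset
  if (!is.null(resample_w)) {
    if (resample_w < 2) mt_invalid_input("resample_w must be >= 2")
    probes <- stats::approx(seq(0, 1, length.out = P$w), probes,
                            xout = seq(0, 1, length.out = resample_w))$y
  }
  pattern1d(probes, index = P$index, roles = P$roles, units = P$units)
}
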