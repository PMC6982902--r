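#' Per-signal time-point candidate from a time pattern
#'
#' Matches a time pattern against the current signal with [h_distance()]
#' and reads off the fitted time shift `b`: because the newest sample
#' (k = 0) is compared against pattern probe `round(b)`, the wrapped `b`
#' is the pattern probe corresponding to the present instant.
#'
#' @param P_time a [pattern1d()] (time role).
#' @param S_i a [one_d_signal()].
#' @param grid a [match_grid()]; defaults to [sync_grid()] for the
#'   pattern's period.
#' @param n matched length.
#' @return List with `b` (probe index in `[1, w]`), `b_raw` (the unrounded
#'   fitted shift) and `h` (the achieved distance).
#' @export
time_point_1d <- function(P_time, S_i, grid = NULL, n = NULL) {
  w <- if (inherits(P_time, "pattern1d")) P_time$w else length(P_time)
  if (is.null(grid)) grid <- sync_grid(w)
  r <- h_distance(P_time, S_i, grid = grid, n = n)
  list(b = wrap_probe(r$match$b, w), b_raw = r$match$b, h = r$h, w = w)
}

#' Aggregate time-point estimate over several candidates
#'
#' Keeps the `n_best` candidates with the lowest matching distance and
#' combines their probe indices by a weighted circular mean over the
#' period (weights proportional to `1 / (h + eps)`). The estimate is
#' flagged reliable only if the best distance does not exceed `h_max`.
#'
#' @param candidates list of candidates from [time_point_1d()] (fields
#'   `b` and `h`).
#' @param w pattern period in probes (taken from the candidates if they
#'   carry it).
#' @param n_best number of best candidates aggregated (default 3).
#' @param h_max reliability threshold on the best distance (default 0.05
#'   on normalized windows).
#' @param eps weight regularizer.
#' @return An object of class `time_point_estimate`: `tau` (probe index in
#'   `[1, w]`, possibly fractional), `reliable`, `h_best`, `candidates`.
#' @export
aggregate_time_point <- function(candidates, w = NULL, n_best = 3,
                                 h_max = 0.05, eps = 1e-9) {
  if (!length(candidates)) mt_invalid_input("no time-point candidates")
  if (is.null(w)) w <- candidates[[1]]$w
  if (is.null(w)) mt_invalid_input("period w unknown")
  hs <- vapply(candidates, function(cnd) cnd$h, numeric(1))
  bs <- vapply(candidates, function(cnd) cnd$b, numeric(1))
  keep <- order(hs)[seq_len(min(n_best, length(hs)))]
  wt <- 1 / (hs[keep] + eps)
  ang <- 2 * pi * (bs[keep] - 1) / w
  tau_ang <- atan2(sum(wt * sin(ang)), sum(wt * cos(ang)))
  tau <- (tau_ang / (2 * pi)) * w
  tau <- (tau %% w) + 1
  structure(list(tau = tau, w = w, reliable = min(hs) <= h_max,
                 h_best = min(hs),
                 candidates = data.frame(b = bs, h = hs)),
            class = "time_point_estimate")
}

#' @export
print.time_point_estimate <- function(x, ...) {
  cat(sprintf("<time_point: tau = %.2f / %d, h_best = %.4g, %s>\n",
              x$tau, x$w, x$h_best,
              if (x$reliable) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Pattern probe index for a sample offset from the present
#'
#' Maps the sample `k_offset` ticks before the newest one to its pattern
#' probe: `ind(k) = wrap(round(tau - k_offset))` into `[1, w]`. Sweeping
#' `k_offset` over `0..w-1` yields a cyclic permutation of `1..w`.
#'
#' @param tau current time point (probe index, possibly fractional).
#' @param k_offset non-negative sample offset into the past.
#' @param w pattern period in probes.
#' @return Integer probe index in `[1, w]`.
#' @export
shape_index <- function(tau, k_offset, w) {
  wrap_probe(round(tau) - k_offset, w)
}

#' Motion-error vector against the shape patterns
#'
#' For each shape pattern, the signed deviation between the current signal
#' and the phase-aligned pattern, averaged over the last `n_avg` samples
#' with linear weights rising from 0 (oldest) to 1 (newest):
#' `e_i = sum_k omega_k (s[m-k] - p[ind(k)]) / sum_k omega_k`.
#'
#' @param shape_patterns list of [pattern1d()] (shape role), indexed like
#'   the signal members they refer to.
#' @param S_cur a [multi_signal()] containing those members.
#' @param tpe a reliable [aggregate_time_point()] estimate; an unreliable
#'   one raises a no-sync error (the caller should skip the tick).
#' @param n_avg number of trailing samples averaged (default 10).
#' @return An object of class `error_vector`: numeric `e` named by signal
#'   index, plus the `mapping` of components to pattern indices.
#' @export
motion_error <- function(shape_patterns, S_cur, tpe, n_avg = 10) {
  if (!inherits(tpe, "time_point_estimate")) mt_invalid_input("tpe must be a time_point_estimate")
  if (!tpe$reliable) mt_nosync_error("time point unreliable; no synchronization this tick")
  k <- 0:(n_avg - 1L)
  wt <- if (n_avg == 1L) 1 else 1 - k / (n_avg - 1)   # newest (k=0) -> 1, oldest -> 0
  e <- vapply(shape_patterns, function(P) {
    i <- as.character(P$index)
    if (!i %in% names(S_cur$signals))
      mt_config_error(sprintf("signal %s missing for shape pattern", i))
    s <- S_cur$signals[[i]]$values
    m <- length(s)
    if (m < n_avg) mt_invalid_input("signal shorter than the averaging window")
    idx <- shape_index(tpe$tau, k, P$w)
    sum(wt * (s[m - k] - P$probes[idx])) / sum(wt)
  }, numeric(1))
  names(e) <- vapply(shape_patterns, function(P) as.character(P$index), character(1))
  structure(list(e = e, mapping = names(e), tau = tpe$tau),
            class = "error_vector")
}

#' @export
print.error_vector <- function(x, ...) {
  cat("<error_vector:", paste(sprintf("e[%s] = %.4g", x$mapping, x$e),
                              collapse = ", "), ">\n")
  invisible(x)
}
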