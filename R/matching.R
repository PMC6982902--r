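#' Search grid for the pattern-matching distance
#'
#' Discrete candidate sets for the four matching parameters: `a` (time
#' scale), `b` (time shift, in pattern probe units), `c` (value scale) and
#' `d` (value offset). Stage 1 of [h_distance()] evaluates the distance on
#' the full Cartesian grid; stage 2 refines local grids (steps divided by
#' `refine_factor`) around the `n_refine_regions` best stage-1 points.
#'
#' @param a_range,b_range,c_range,d_range numeric length-2 `(min, max)`.
#' @param a_card,b_card,c_card,d_card number of candidates per parameter.
#' @param refine_factor grid-step divisor for the refinement stage.
#' @param n_refine_regions number of stage-1 minima refined in stage 2.
#' @param refine_span half-width of each local refinement grid, in coarse
#'   steps (default 2).
#' @return An object of class `match_grid`. Its `n_stage1` field is the
#'   stage-1 evaluation count (the product of the four cardinalities).
#' @export
match_grid <- function(a_range = c(0.7, 1.3), a_card = 30,
                       b_range = c(1, 200), b_card = 20,
                       c_range = c(0.7, 1.3), c_card = 15,
                       d_range = c(-0.3, 0.3), d_card = 25,
                       refine_factor = 5, n_refine_regions = 3,
                       refine_span = 2) {
  chk <- function(rng, card, nm) {
    if (length(rng) != 2L || rng[1] > rng[2])
      mt_invalid_input(sprintf("%s_range must be (min, max)", nm))
    if (card < 1) mt_invalid_input(sprintf("%s_card must be >= 1", nm))
  }
  chk(a_range, a_card, "a"); chk(b_range, b_card, "b")
  chk(c_range, c_card, "c"); chk(d_range, d_card, "d")
  g <- structure(list(
    a = list(range = a_range, card = as.integer(a_card)),
    b = list(range = b_range, card = as.integer(b_card)),
    c = list(range = c_range, card = as.integer(c_card)),
    d = list(range = d_range, card = as.integer(d_card)),
    refine_factor = as.integer(refine_factor),
    n_refine_regions = as.integer(n_refine_regions),
    refine_span = refine_span),
    class = "match_grid")
  g$n_stage1 <- as.integer(prod(vapply(g[c("a", "b", "c", "d")],
                                       function(p) p$card, numeric(1))))
  g
}

#' @export
print.match_grid <- function(x, ...) {
  cat(sprintf("<match_grid: %dx%dx%dx%d = %d stage-1 evaluations, refine 1/%d x %d regions>\n",
              x$a$card, x$b$card, x$c$card, x$d$card, x$n_stage1,
              x$refine_factor, x$n_refine_regions))
  invisible(x)
}

grid_candidates <- function(p) {
  if (p$card == 1L) mean(p$range) else seq(p$range[1], p$range[2], length.out = p$card)
}

grid_step <- function(p) {
  if (p$card == 1L) 0 else (p$range[2] - p$range[1]) / (p$card - 1)
}

#' Default grid for normalized matching
#'
#' With both windows normalized to the fixed `(-0.6, 0.6)` band, the useful
#' value-scale and value-offset ranges collapse to narrow neighbourhoods of
#' `(1, 0)`, which brings the stage-1 evaluation count down from the full
#' grid's quarter-million to a few thousand.
#'
#' @param w pattern period in samples (sets the time-shift range).
#' @param full if `TRUE`, return the unreduced grid with the historical
#'   cardinalities 30 x 20 x 15 x 25.
#' @return A [match_grid()].
#' @export
default_grid <- function(w, full = FALSE) {
  if (full)
    match_grid(b_range = c(1, w), b_card = 20)
  else
    match_grid(a_range = c(0.7, 1.3), a_card = 30,
               b_range = c(1, w), b_card = 20,
               c_range = c(0.85, 1.15), c_card = 3,
               d_range = c(-0.15, 0.15), d_card = 3)
}

#' Grid tuned for time-point (phase) estimation
#'
#' Finer time-shift resolution and a narrower tempo band than
#' [default_grid()], for synchronization where the quantity of interest is
#' the fitted shift `b`.
#'
#' @param w pattern period in samples.
#' @return A [match_grid()].
#' @export
sync_grid <- function(w) {
  match_grid(a_range = c(0.85, 1.15), a_card = 15,
             b_range = c(1, w), b_card = 40,
             c_range = c(0.85, 1.15), c_card = 3,
             d_range = c(-0.15, 0.15), d_card = 3)
}

#' Normalize a signal window to the fixed comparison band
#'
#' Linear map `s_norm = zeta * s + eta` sending the window's `(min, max)`
#' onto `(-0.6, +0.6)`. A constant window cannot be normalized; it is
#' returned as all zeros with `zeta = 0` and the `degenerate` flag set.
#'
#' @param values numeric vector, length >= 2.
#' @return List with `values`, `zeta`, `eta`, `degenerate`.
#' @export
normalize_window <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) mt_invalid_input("window must have at least 2 samples")
  lo <- min(values); hi <- max(values)
  if (hi == lo)
    return(list(values = rep(0, length(values)), zeta = 0, eta = 0, degenerate = TRUE))
  zeta <- 1.2 / (hi - lo)
  eta <- -0.6 - zeta * lo
  list(values = zeta * values + eta, zeta = zeta, eta = eta, degenerate = FALSE)
}

# Pattern probe index for matched sample k (k = 0 is the newest signal
# sample): round(b - a k) wrapped cyclically into [1, w].
wrap_probe <- function(i, w) ((round(i) - 1) %% w) + 1

#' Mean-squared pattern-signal distance at fixed transform parameters
#'
#' Compares the last `n` samples of the signal against the pattern read
#' cyclically at probe `b - a k` (rounded, wrapped into the period), after
#' scaling the pattern values by `c` and shifting them by `d`:
#' `g = mean_k (c * P[wrap(round(b - a k))] + d - s[m - k])^2`, k = 0..n-1.
#'
#' @param P a [pattern1d()] or numeric probe vector.
#' @param S a [one_d_signal()] or numeric sample vector.
#' @param a,b,c,d transform parameters (time scale/shift, value scale/offset).
#' @param n matched length in samples; must not exceed the signal length.
#' @return Non-negative scalar distance.
#' @export
g_distance <- function(P, S, a, b, c, d, n = NULL) {
  p <- pattern_probes(P)
  s <- signal_values(S)
  w <- length(p); m <- length(s)
  if (is.null(n)) n <- min(m, w)
  if (n < 1) mt_invalid_input("n must be >= 1")
  if (n > m) mt_invalid_input("matched length n exceeds the signal length")
  k <- 0:(n - 1)
  idx <- wrap_probe(b - a * k, w)
  mean((p[idx] * c + d - s[m - k])^2)
}

pattern_probes <- function(P) {
  if (inherits(P, "pattern1d")) P$probes else as.numeric(P)
}

signal_values <- function(S) {
  if (inherits(S, "one_d_signal")) S$values else as.numeric(S)
}

# Evaluate g over the Cartesian product of candidate vectors. Exploits the
# fact that for fixed (a, b) the distance is a quadratic polynomial in
# (c, d) whose coefficients are five moments of the aligned windows, so the
# full (c, d) sheet costs O(1) per point after an O(n) moment pass.
# Returns the grid minimum, its parameters, and the evaluation count.
eval_grid <- function(p, swin, a_v, b_v, c_v, d_v) {
  w <- length(p); n <- length(swin)
  ab <- expand.grid(a = a_v, b = b_v, KEEP.OUT.ATTRS = FALSE)
  k <- 0:(n - 1)
  # n x nab matrix of pattern values aligned to each (a, b) candidate
  idx <- wrap_probe(rep(ab$b, each = n) - outer(k, ab$a), w)
  pm <- matrix(p[idx], nrow = n)
  srev <- swin[n - k]                      # s[m - k], newest first
  pp <- colMeans(pm * pm)
  ps <- colMeans(pm * srev)
  p1 <- colMeans(pm)
  s1 <- mean(srev); ss <- mean(srev * srev)
  cd <- expand.grid(c = c_v, d = d_v, KEEP.OUT.ATTRS = FALSE)
  # g[cd, ab] = c^2 pp - 2 c ps + 2 c d p1 + (d^2 - 2 d s1 + ss)
  G <- outer(cd$c^2, pp) - 2 * outer(cd$c, ps) + 2 * outer(cd$c * cd$d, p1) +
    (cd$d^2 - 2 * cd$d * s1 + ss)
  G[G < 0] <- 0                            # guard against round-off
  i <- arrayInd(which.min(G), dim(G))
  list(g = G[i[1], i[2]],
       a = ab$a[i[2]], b = ab$b[i[2]], c = cd$c[i[1]], d = cd$d[i[1]],
       n_eval = length(G),
       ab = ab, cd = cd, G = G)
}

match_result <- function(a, b, c, d, g_value, n, n_eval_stage1 = NA, n_eval_stage2 = NA) {
  structure(list(a = a, b = b, c = c, d = d, g_value = g_value, n = n,
                 n_eval_stage1 = n_eval_stage1, n_eval_stage2 = n_eval_stage2),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match: g = %.4g at a = %.4g, b = %.4g, c = %.4g, d = %.4g (n = %d)>\n",
              x$g_value, x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Best-matching distance between a pattern and a signal
#'
#' Minimizes [g_distance()] over the four transform parameters with a
#' two-stage coarse-to-fine search: stage 1 scans the full candidate grid;
#' the `n_refine_regions` lowest stage-1 points (deduplicated so seeds are
#' at least two coarse steps apart in the `(a, b)` plane) each seed a local
#' grid spanning one coarse step on either side with steps divided by
#' `refine_factor`. The returned minimum therefore never exceeds the
#' stage-1 minimum.
#'
#' Both compared windows are normalized to the `(-0.6, 0.6)` band by
#' default, which is what makes the reduced `(c, d)` ranges of
#' [default_grid()] sufficient; set `normalize = FALSE` to match in raw
#' units (then the fitted `c, d` are the generating value transform).
#'
#' @param P a [pattern1d()] or numeric probe vector.
#' @param S a [one_d_signal()] or numeric vector; the last `n` samples are
#'   the compared window.
#' @param grid a [match_grid()]; defaults to `default_grid(w)`.
#' @param n matched length, default `min(m, w)`.
#' @param normalize normalize both windows before the search.
#' @return List with `h` (the minimum) and `match` (a `match_result`
#'   carrying the fitted parameters and the per-stage evaluation counts).
#' @export
h_distance <- function(P, S, grid = NULL, n = NULL, normalize = TRUE) {
  p <- pattern_probes(P)
  s <- signal_values(S)
  w <- length(p); m <- length(s)
  if (is.null(n)) n <- min(m, w)
  if (n < 1) mt_invalid_input("n must be >= 1")
  if (n > m) mt_invalid_input("matched length n exceeds the signal length")
  if (is.null(grid)) grid <- default_grid(w)
  swin <- s[(m - n + 1):m]
  if (normalize) {
    p <- normalize_window(p)$values
    swin <- normalize_window(swin)$values
  }

  a_v <- grid_candidates(grid$a); b_v <- grid_candidates(grid$b)
  c_v <- grid_candidates(grid$c); d_v <- grid_candidates(grid$d)
  s1 <- eval_grid(p, swin, a_v, b_v, c_v, d_v)
  n1 <- s1$n_eval

  seeds <- pick_refine_seeds(s1, grid)
  best <- s1[c("g", "a", "b", "c", "d")]
  n2 <- 0L
  span <- if (is.null(grid$refine_span)) 2 else grid$refine_span
  for (sd in seeds) {
    loc <- lapply(c("a", "b", "c", "d"), function(nm) {
      local_candidates(sd[[nm]], grid[[nm]], grid$refine_factor, span)
    })
    r <- eval_grid(p, swin, loc[[1]], loc[[2]], loc[[3]], loc[[4]])
    n2 <- n2 + r$n_eval
    if (r$g < best$g) best <- r[c("g", "a", "b", "c", "d")]
  }
  m_res <- match_result(best$a, best$b, best$c, best$d, best$g, n,
                        n_eval_stage1 = n1, n_eval_stage2 = n2)
  list(h = best$g, match = m_res)
}

# Fine candidates around a seed: seed + j * (coarse step / refine_factor),
# j = -span*refine..span*refine, clipped to the parameter range.
local_candidates <- function(center, p, refine_factor, span) {
  st <- grid_step(p)
  if (st == 0) return(center)
  fine <- st / refine_factor
  r <- span * refine_factor
  v <- center + (-r:r) * fine
  unique(pmin(pmax(v, p$range[1]), p$range[2]))
}

# Lowest-g stage-1 points, deduplicated: each kept seed differs from every
# previously kept one by >= 2 coarse steps in a or in b.
pick_refine_seeds <- function(s1, grid) {
  ord <- order(s1$G)
  dim_g <- dim(s1$G)
  a_st <- grid_step(grid$a); b_st <- grid_step(grid$b)
  seeds <- list()
  for (o in ord) {
    if (length(seeds) >= grid$n_refine_regions) break
    i <- arrayInd(o, dim_g)
    cand <- list(g = s1$G[i[1], i[2]],
                 a = s1$ab$a[i[2]], b = s1$ab$b[i[2]],
                 c = s1$cd$c[i[1]], d = s1$cd$d[i[1]])
    ok <- TRUE
    for (sd in seeds) {
      da <- if (a_st > 0) abs(cand$a - sd$a) / a_st else 0
      db <- if (b_st > 0) abs(cand$b - sd$b) / b_st else 0
      if (da < 2 && db < 2) { ok <- FALSE; break }
    }
    if (ok) seeds[[length(seeds) + 1L]] <- cand
  }
  seeds
}

#' Exhaustive reference minimizer for the matching distance
#'
#' Evaluates [g_distance()] on the fully refined grid: every parameter at
#' the stage-2 resolution (`coarse step / refine_factor`) across its whole
#' range. Intended as an independent check of [h_distance()] on grids small
#' enough for exhaustion; the two-stage search can never beat it.
#'
#' @inheritParams h_distance
#' @return List with `h` and `match`, as [h_distance()].
#' @export
h_oracle <- function(P, S, grid, n = NULL, normalize = TRUE) {
  p <- pattern_probes(P)
  s <- signal_values(S)
  w <- length(p); m <- length(s)
  if (is.null(n)) n <- min(m, w)
  if (n > m) mt_invalid_input("matched length n exceeds the signal length")
  swin <- s[(m - n + 1):m]
  if (normalize) {
    p <- normalize_window(p)$values
    swin <- normalize_window(swin)$values
  }
  fine <- function(pdef) {
    if (pdef$card == 1L) return(mean(pdef$range))
    npts <- (pdef$card - 1L) * grid$refine_factor + 1L
    seq(pdef$range[1], pdef$range[2], length.out = npts)
  }
  r <- eval_grid(p, swin, fine(grid$a), fine(grid$b), fine(grid$c), fine(grid$d))
  list(h = r$g,
       match = match_result(r$a, r$b, r$c, r$d, r$g, n,
                            n_eval_stage1 = r$n_eval, n_eval_stage2 = 0L))
}
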