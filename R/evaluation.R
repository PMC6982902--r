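#' RMSE of a position signal against its phase-aligned shape pattern
#'
#' `RMSE = sqrt(mean((s_k - p_ind(k))^2))` over a sample range, where
#' `ind(k)` is the pattern probe corresponding to signal sample `k`,
#' supplied as a per-sample time-point series (from the teaching-session
#' log or any synchronization run).
#'
#' @param s a [one_d_signal()] or numeric vector (metres).
#' @param P_shape the [pattern1d()] shape reference (metres).
#' @param tau_series numeric vector, same length as the signal: the time
#'   point (pattern probe, possibly fractional) at every sample.
#' @param range integer sample range (vector of indices) over which to
#'   evaluate; must be non-empty.
#' @param units_scale multiplier from signal units to reported units
#'   (default 1000: metres in, millimetres out).
#' @return RMSE in reported units (mm by default).
#' @export
rmse_signal <- function(s, P_shape, tau_series, range = NULL, units_scale = 1000) {
  x <- signal_values(s)
  if (is.null(range)) range <- seq_along(x)
  if (!length(range)) mt_invalid_input("empty evaluation range")
  if (length(tau_series) != length(x))
    mt_invalid_input("tau_series must cover the whole signal")
  w <- P_shape$w
  idx <- wrap_probe(tau_series[range], w)
  dev <- x[range] - P_shape$probes[idx]
  sqrt(mean(dev^2)) * units_scale
}

#' Aggregate accuracy score E1
#'
#' The arithmetic mean of the per-signal RMSEs, evaluated on the central
#' portion of the test-phase signal (by default samples from 0.3 to 0.9 of
#' the total length).
#'
#' @param S a [multi_signal()] of position signals.
#' @param shape_patterns list of [pattern1d()] matching the member indices.
#' @param tau_series per-sample time-point series.
#' @param frac numeric `(lo, hi)` fractions of the signal length.
#' @param units_scale see [rmse_signal()].
#' @return List with `E1` (mm), `rmse_per_signal`, `range`.
#' @export
e1_score <- function(S, shape_patterns, tau_series, frac = c(0.3, 0.9),
                     units_scale = 1000) {
  m <- S$n_samples
  range <- seq.int(max(1L, ceiling(frac[1] * m)), floor(frac[2] * m))
  rmses <- vapply(shape_patterns, function(P) {
    rmse_signal(S$signals[[as.character(P$index)]], P, tau_series, range,
                units_scale)
  }, numeric(1))
  names(rmses) <- vapply(shape_patterns, function(P) as.character(P$index), character(1))
  list(E1 = mean(rmses), rmse_per_signal = rmses, range = base::range(range))
}

#' Classification-selected accuracy score E2
#'
#' Finds the longest contiguous interval of the class timeline labelled
#' only with the regulator class (`"Calpha"`), and evaluates the E1-style
#' mean RMSE on a fixed-length window (default 30 s) starting at that
#' interval's beginning. Equal-length candidate intervals resolve to the
#' earliest. The window is truncated (and flagged) if it overruns the
#' recording.
#'
#' @param S,shape_patterns,tau_series,units_scale as in [e1_score()].
#' @param timeline character vector of per-sample class labels covering
#'   the signal.
#' @param window_s window length in seconds.
#' @return List with `E2` (mm), `rmse_per_signal`, `window_start` (sample),
#'   `truncated`.
#' @export
e2_score <- function(S, shape_patterns, tau_series, timeline, window_s = 30,
                     units_scale = 1000) {
  m <- S$n_samples
  if (length(timeline) != m) mt_invalid_input("timeline must cover the signal")
  is_a <- timeline == "Calpha"
  if (!any(is_a)) mt_stop("mt_undefined_e2", "no Calpha interval in the timeline")
  r <- rle(is_a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  a_runs <- which(r$values)
  best <- a_runs[which.max(r$lengths[a_runs])]   # ties: which.max takes the earliest
  w_start <- starts[best]
  w_len <- round(window_s * S$sample_rate)
  w_end <- min(m, w_start + w_len - 1L)
  range <- seq.int(w_start, w_end)
  rmses <- vapply(shape_patterns, function(P) {
    rmse_signal(S$signals[[as.character(P$index)]], P, tau_series, range,
                units_scale)
  }, numeric(1))
  names(rmses) <- vapply(shape_patterns, function(P) as.character(P$index), character(1))
  list(E2 = mean(rmses), rmse_per_signal = rmses,
       window_start = w_start, truncated = (w_end - w_start + 1L) < w_len)
}

#' Learning-progress score E3
#'
#' `E3 = E2_test - beta * E2_pre`: the test-phase score discounted by a
#' fraction of the pre-learning score. May be negative by construction.
#'
#' @param e2_test,e2_pre E2 scores (mm) from the test and early phases,
#'   computed with identical settings.
#' @param beta discount weight (default 0.25).
#' @return E3 in mm.
#' @export
e3_score <- function(e2_test, e2_pre, beta = 0.25) {
  e2_test - beta * e2_pre
}

#' Mean and sample standard deviation of a group
#'
#' @param values numeric vector, length >= 2.
#' @return List with `mean` and `sd` (n-1 denominator).
#' @export
group_stats <- function(values) {
  if (length(values) < 2L) mt_invalid_input("need at least 2 values")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Monte-Carlo critical value of the Shapiro-Wilk statistic
#'
#' The lower 5th (or `alpha`) percentile of the W statistic under the
#' normal null for a given sample size, estimated by seeded simulation.
#' Small-sample tabulated values vary across sources, so the package
#' computes its own.
#'
#' @param n sample size per draw.
#' @param alpha lower tail probability (default 0.05).
#' @param n_draws number of null samples.
#' @param seed RNG seed (local to the call).
#' @return The empirical `alpha` quantile of W.
#' @export
sw_critical_value <- function(n, alpha = 0.05, n_draws = 1e5, seed = 1L) {
  with_seed(seed, {
    ws <- vapply(seq_len(n_draws), function(i) {
      stats::shapiro.test(stats::rnorm(n))$statistic
    }, numeric(1))
    as.numeric(stats::quantile(ws, alpha, names = FALSE))
  })
}

# classic mean-centered Levene statistic: one-way ANOVA F on the absolute
# deviations from the group means
levene_statistic <- function(g1, g2) {
  z <- c(abs(g1 - mean(g1)), abs(g2 - mean(g2)))
  grp <- factor(rep(c(1, 2), c(length(g1), length(g2))))
  fit <- stats::anova(stats::lm(z ~ grp))
  list(statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       df = c(1L, length(z) - 2L))
}

#' Statistical battery comparing two learning methods
#'
#' Runs the analysis sequence used to compare efficiency scores between an
#' adaptive (classification-driven) and a fixed teaching method: per-group
#' Shapiro-Wilk normality statistics, the classic mean-centered Levene
#' test of variance homogeneity, and a pooled-variance two-sample Student
#' t test with a one-sided alternative (group 1 mean below group 2 mean),
#' together with the relevant critical values at the chosen level.
#'
#' @param group1,group2 numeric score vectors (n >= 3 each); group 1 is
#'   the method hypothesized to score lower (better).
#' @param alpha significance level (default 0.05).
#' @param sw_draws Monte-Carlo draws for the Shapiro-Wilk critical value;
#'   `0` skips it (`NA` returned).
#' @param seed seed for the Monte-Carlo critical value.
#' @return An object of class `stat_report`.
#' @export
test_battery <- function(group1, group2, alpha = 0.05, sw_draws = 20000,
                         seed = 1L) {
  if (length(group1) < 3L || length(group2) < 3L)
    mt_invalid_input("each group needs at least 3 values")
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (v1 == 0 && v2 == 0) mt_stop("mt_test_undefined", "both groups degenerate")
  n1 <- length(group1); n2 <- length(group2)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  t_stat <- (mean(group2) - mean(group1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_one_sided <- stats::pt(t_stat, df, lower.tail = FALSE)
  lev <- levene_statistic(group1, group2)
  sw1 <- stats::shapiro.test(group1)
  sw2 <- stats::shapiro.test(group2)
  sw_crit <- if (sw_draws > 0)
    sw_critical_value(min(n1, n2), alpha, n_draws = sw_draws, seed = seed)
  else NA_real_
  structure(list(
    group1 = group_stats(group1), group2 = group_stats(group2),
    n = c(n1, n2),
    shapiro_w = c(group1 = unname(sw1$statistic), group2 = unname(sw2$statistic)),
    shapiro_crit = sw_crit,
    levene = lev$statistic,
    levene_crit = stats::qf(1 - alpha, 1, df),
    t = t_stat, df = df, p = p_one_sided,
    t_crit = stats::qt(1 - alpha, df),
    alpha = alpha),
    class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report: t(%d) = %.3f (crit %.3f), one-sided p = %.3f>\n",
              x$df, x$t, x$t_crit, x$p))
  cat(sprintf("  means %.1f vs %.1f; sd %.1f vs %.1f; Levene %.2f (crit %.2f); S-W %.2f/%.2f (crit %s)\n",
              x$group1$mean, x$group2$mean, x$group1$sd, x$group2$sd,
              x$levene, x$levene_crit,
              x$shapiro_w[1], x$shapiro_w[2],
              if (is.na(x$shapiro_crit)) "-" else sprintf("%.2f", x$shapiro_crit)))
  invisible(x)
}

#' Bundled participant efficiency scores
#'
#' Loads the packaged fixture of per-participant efficiency scores (E1,
#' E2, E3 in mm) for the two teaching methods: method 1 selects the
#' algorithm by signal classification, method 2 uses the fixed regulator
#' algorithm throughout.
#'
#' @param path override the bundled CSV (columns `parameter, method,
#'   participant, value_mm`).
#' @return data.frame.
#' @export
load_efficiency_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table3.csv", package = "motionteach")
  if (!nzchar(path) || !file.exists(path)) mt_parse_error("fixture CSV not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Full efficiency-score analysis report
#'
#' Applies [group_stats()] and [test_battery()] to every efficiency
#' parameter in a per-participant score table.
#'
#' @param scores data.frame with columns `parameter`, `method` (1 or 2),
#'   `participant`, `value_mm` (see [load_efficiency_fixture()]).
#' @param alpha significance level.
#' @param sw_draws,seed passed to [test_battery()].
#' @return Named list (by parameter) of `stat_report` objects, class
#'   `efficiency_analysis`.
#' @export
efficiency_analysis <- function(scores, alpha = 0.05, sw_draws = 20000,
                                seed = 1L) {
  need <- c("parameter", "method", "value_mm")
  if (!all(need %in% names(scores)))
    mt_parse_error(paste("scores needs columns:", paste(need, collapse = ", ")))
  params <- unique(scores$parameter)
  out <- lapply(params, function(p) {
    g1 <- scores$value_mm[scores$parameter == p & scores$method == 1]
    g2 <- scores$value_mm[scores$parameter == p & scores$method == 2]
    test_battery(g1, g2, alpha = alpha, sw_draws = sw_draws, seed = seed)
  })
  names(out) <- params
  structure(out, class = "efficiency_analysis")
}

#' @export
print.efficiency_analysis <- function(x, ...) {
  for (p in names(x)) {
    cat(p, ": ", sep = "")
    print(x[[p]])
  }
  invisible(x)
}
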