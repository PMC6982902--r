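#' Write sensor streams to CSV
#'
#' Schema: `t, sensor_id, ax, ay, az, qx, qy, qz, qw`; time in seconds,
#' numeric columns at 9 significant digits (the declared round-trip
#' precision).
#'
#' @param streams a [sensor_stream()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stream <- function(streams, path) {
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  tabs <- lapply(streams, function(s) {
    tt <- (0:(s$n_samples - 1)) / s$sample_rate
    data.table::data.table(
      t = signif(tt, 9), sensor_id = s$sensor_id,
      ax = signif(s$accel[, 1], 9), ay = signif(s$accel[, 2], 9),
      az = signif(s$accel[, 3], 9),
      qx = signif(s$quats[, 1], 9), qy = signif(s$quats[, 2], 9),
      qz = signif(s$quats[, 3], 9), qw = signif(s$quats[, 4], 9))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read sensor streams from CSV
#'
#' Inverse of [write_stream()]; the sample rate is recovered from the
#' median time step. A missing column is a parse error naming the column.
#'
#' @param path CSV file in the documented schema.
#' @return Named list of [sensor_stream()] objects, one per `sensor_id`.
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) mt_parse_error(sprintf("no such file: %s", path))
  dt <- data.table::fread(path)
  need <- c("t", "sensor_id", "ax", "ay", "az", "qx", "qy", "qz", "qw")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    mt_parse_error(paste("stream CSV missing column(s):",
                         paste(missing_cols, collapse = ", ")))
  out <- list()
  for (sid in unique(dt$sensor_id)) {
    d <- dt[dt$sensor_id == sid, ]
    rate <- 1 / stats::median(diff(d$t))
    out[[as.character(sid)]] <- sensor_stream(
      sid, unname(as.matrix(d[, c("ax", "ay", "az")])),
      unname(as.matrix(d[, c("qx", "qy", "qz", "qw")])),
      sample_rate = round(rate, 6))
  }
  out
}

BANK_FORMAT_VERSION <- "1.0"

#' Write a pattern bank to JSON
#'
#' Schema: `{format_version, label_set, entries: [{label, patterns:
#' {index: {w, roles, units, probes[]}}}]}`.
#'
#' @param bank a [pattern_bank()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  if (!inherits(bank, "pattern_bank")) mt_invalid_input("bank must be a pattern_bank")
  entries <- lapply(seq_len(bank$n_pairs), function(u) {
    e <- bank$entries[[u]]
    pats <- lapply(e$members, function(p)
      list(w = p$w, roles = as.list(p$roles),
           units = if (is.null(p$units)) NULL else p$units,
           probes = p$probes))
    list(label = bank$labels[u], patterns = pats)
  })
  jsonlite::write_json(list(format_version = BANK_FORMAT_VERSION,
                            label_set = as.list(bank$label_set),
                            entries = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pattern bank from JSON
#'
#' @param path bank file written by [write_bank()]; an unknown
#'   `format_version` is an error.
#' @return A [pattern_bank()].
#' @export
read_bank <- function(path) {
  if (!file.exists(path)) mt_parse_error(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$format_version) || j$format_version != BANK_FORMAT_VERSION)
    mt_parse_error(sprintf("unknown bank format_version: %s",
                           if (is.null(j$format_version)) "<missing>" else j$format_version))
  entries <- lapply(j$entries, function(e) {
    members <- lapply(names(e$patterns), function(i) {
      p <- e$patterns[[i]]
      pattern1d(unlist(p$probes), index = as.integer(i),
                roles = unlist(p$roles) %||% character(),
                units = p$units)
    })
    pattern_md(members, label = e$label)
  })
  pattern_bank(entries, label_set = unlist(j$label_set))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SESSION_CONFIG_KEYS <- c(
  "selection", "fc", "period_w", "grid", "sync_grid", "k", "h_max",
  "n_best", "n_avg", "actuators", "len", "elaps", "cbeta", "sync_every",
  "hysteresis", "gate_indices", "eval_frac", "eval_window_s", "beta",
  "seed", "learner")

#' Read and validate a session configuration (YAML or JSON)
#'
#' Strict on key names: an unknown top-level key is a configuration error,
#' so typos in hand-edited files surface immediately.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values.
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) mt_parse_error(sprintf("no such file: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), SESSION_CONFIG_KEYS)
  if (length(unknown))
    mt_config_error(paste("unknown session config key(s):",
                          paste(unknown, collapse = ", ")))
  cfg
}

#' Write a classification timeline CSV
#'
#' Columns `t_start, t_end, label, min_dist`, one row per decision.
#'
#' @param timeline data.frame in that schema.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  data.table::fwrite(timeline, path)
  invisible(path)
}
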