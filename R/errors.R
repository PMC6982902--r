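# Condition constructors shared by all modules. Every error raised by the
# package carries the "motionteach_error" class plus a specific subclass so
# callers (and tests) can discriminate failure modes without string matching.

mt_stop <- function(subclass, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(subclass, "motionteach_error", "error", "condition")))
}

mt_invalid_input <- function(msg) mt_stop("mt_invalid_input", msg)
mt_invalid_kind  <- function(msg) mt_stop("mt_invalid_kind", msg)
mt_config_error  <- function(msg) mt_stop("mt_config_error", msg)
mt_segment_error <- function(msg) mt_stop("mt_segment_error", msg)
mt_nosync_error  <- function(msg) mt_stop("mt_nosync_error", msg)
mt_parse_error   <- function(msg) mt_stop("mt_parse_error", msg)
mt_degenerate    <- function(msg) mt_stop("mt_degenerate_error", msg)

# Run an expression under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL runs as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
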