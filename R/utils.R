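# Internal helpers: classed conditions and seeded evaluation.

stop_pavpan <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pavpan_error", "error")))
}

abort_config <- function(msg) stop_pavpan(msg, "pavpan_config_error")
abort_validation <- function(msg) stop_pavpan(msg, "pavpan_validation_error")
abort_calibration <- function(msg) stop_pavpan(msg, "pavpan_calibration_error")
abort_io <- function(msg) stop_pavpan(msg, "pavpan_io_error")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("`seed` must be a single non-missing number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort_config(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort_config(sprintf(
      "`%s` must be a single number in %s%g, %g%s", name,
      if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"
    ))
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
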