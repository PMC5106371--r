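# Internal helpers: classed conditions and scoped RNG.

stop_laterace <- function(message, class) {
  stop(errorCondition(message, class = c(class, "laterace_error")))
}

stop_insufficient <- function(message) {
  stop_laterace(message, "laterace_insufficient_data")
}

stop_degenerate <- function(message) {
  stop_laterace(message, "laterace_degenerate")
}

stop_domain <- function(message) {
  stop_laterace(message, "laterace_domain")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_domain("seed must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_intervals <- function(intervals, min_n = 3L, what = "intervals") {
  if (!is.numeric(intervals)) stop_domain(sprintf("%s must be numeric", what))
  if (anyNA(intervals) || any(!is.finite(intervals))) {
    stop_domain(sprintf("%s must be finite and non-missing", what))
  }
  if (length(intervals) < min_n) {
    stop_insufficient(sprintf("need at least %d %s, got %d",
                              min_n, what, length(intervals)))
  }
  if (any(intervals <= 0)) {
    stop_domain(sprintf("%s must be strictly positive", what))
  }
  invisible(intervals)
}
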