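# Internal helpers: classed conditions and seeded evaluation.

ptt_error <- function(message, class = "pttdose_invalid_input") {
  stop(structure(
    class = c(class, "pttdose_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, strict_lower = FALSE) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) ||
      (!allow_na && is.na(x))) {
    ptt_error(sprintf("`%s` must be a single finite number", name))
  }
  if (is.na(x)) return(invisible(x))
  if (strict_lower) {
    if (x <= lower) ptt_error(sprintf("`%s` must be > %g", name, lower))
  } else if (x < lower) {
    ptt_error(sprintf("`%s` must be >= %g", name, lower))
  }
  if (x > upper) ptt_error(sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}

# Evaluate fn() with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
run_seeded <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    ptt_error("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
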