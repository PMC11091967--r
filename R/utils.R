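# Internal helpers.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# session RNG stream.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix-free, sprintf-style message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                         closedLower = TRUE, closedUpper = TRUE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (closedLower) x >= lower else x > lower) &&
    (if (closedUpper) x <= upper else x < upper)
  if (!ok) stopf("'%s' out of range", name)
  invisible(as.numeric(x))
}
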