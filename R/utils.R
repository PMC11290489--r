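# internal helpers: typed conditions and seeded evaluation

.sbaStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sba_error", "error", "condition")))
}

.validationError <- function(msg) .sbaStop(msg, "sba_validation_error")
.calibrationError <- function(msg) .sbaStop(msg, "sba_calibration_error")
.degenerateError <- function(msg) .sbaStop(msg, "sba_degenerate_error")
.joinError <- function(msg) .sbaStop(msg, "sba_join_error")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .validationError(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    .validationError(sprintf("'%s' = %g is out of range", name, x))
  }
  invisible(x)
}
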