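# internal helpers

stopf <- function(fmt, ..., class = "strugglescope_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

# seed scoping: run expr with a fixed seed without clobbering the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# trapezoidal integral of y over t (both numeric, same length)
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-n] + y[-1L]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
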