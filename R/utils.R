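`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x)
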