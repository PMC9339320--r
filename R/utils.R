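# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed seed and restore the caller's RNG state.
# Used for common-random-number objective evaluation so that all candidate
# plans in a local search see identical Monte-Carlo noise.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Draw a seed usable by set.seed from the current RNG stream.
drawSeed <- function() sample.int(.Machine$integer.max - 1L, 1L)

rowMins <- function(m) do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
rowMaxs <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

formatError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pvlas_format_error", "error")))
}

argError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pvlas_argument_error", "error")))
}
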