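#' @keywords internal
"_PACKAGE"

# Run code with a temporarily fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("spotcode_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
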