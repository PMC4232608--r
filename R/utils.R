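#' Derive a reproducible sub-seed from a base seed and a label
#'
#' All stochastic stages of the pipeline draw their randomness from
#' sub-seeds derived from one global seed by stable string hashing, so a
#' run is reproducible regardless of stage order.
#'
#' @param seed Integer base seed.
#' @param label Character label of the stage or stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, keeps everything in 32-bit integer range
  h <- as.double(seed %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  Generators use this so they are deterministic per
# (preset, seed) and leave no global side effects.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix for user input errors
abort_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
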