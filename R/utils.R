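#' Run code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded helpers do not perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic stream splitting: child seeds stay below 2^31 - 1 and are
#' exactly representable in double precision throughout.
#'
#' @param seed master seed (integer < 2^31).
#' @param i stream index (non-negative integer).
#' @return an integer seed.
#' @keywords internal
subSeed <- function(seed, i) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  as.integer(((s * 48271) %% m + (as.double(i) * 7919) %% m) %% m)
}

# stop() with sprintf formatting, no call in message
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
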