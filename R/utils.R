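#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded pipeline stages never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministically derive a sub-seed from a master seed; kept below 2^31
## so it is a valid R integer seed.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(offset)) %% 2147483647L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
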