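#' @keywords internal
"_PACKAGE"

## Seed discipline: every stochastic operation takes an integer seed, runs
## under a locally scoped RNG state, and restores the caller's state on exit.
## Sub-streams are derived arithmetically so that one run seed drives the
## whole pipeline without global side effects.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

#' Derive a sub-stream seed from a run seed
#'
#' Deterministic arithmetic derivation keeping the result a valid 32-bit
#' integer, so that one user-facing seed can drive several independent
#' stochastic stages.
#'
#' @param seed integer run seed.
#' @param offset integer stream index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  s <- (abs(as.double(seed)) + 104729 * (abs(as.double(offset)) + 1)) %%
    2147483587
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pp <- function(...) stop(..., call. = FALSE)

## quantile convention used throughout: linear interpolation (type 7)
qr_quantile <- function(x, p) stats::quantile(x, p, na.rm = TRUE,
                                              names = FALSE, type = 7)
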