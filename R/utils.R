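## Internal helpers: error signalling, seed splitting, small validators.

stop_eegdann <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "eegdann_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Derive a child seed from a master seed and integer stream indices
#'
#' All randomness in the package flows from one explicit integer seed.
#' Substreams (per subject, per burst process, per annotator) are derived by a
#' counter-based mixing scheme so that any subset of a cohort can be
#' regenerated independently of the rest.
#'
#' @param seed master integer seed.
#' @param ... non-negative integer stream indices (e.g. subject index,
#'   component index).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in seq_along(idx)) {
    # affine mix per index; constants are arbitrary odd multipliers
    h <- (h * 48271 + (as.numeric(idx[k]) + 1) * 16807 + k * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

is_binary <- function(x) {
  all(x %in% c(0L, 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
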