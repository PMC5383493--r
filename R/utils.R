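#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the generator seeded at `seed`, restoring the caller's RNG
#' state afterwards so library internals never perturb user-level streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
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
  set.seed(as.integer(seed))
  expr
}

# One master seed streams per-stage/per-layer sub-seeds by fixed offsets.
# Kept well below .Machine$integer.max for small master seeds.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_burnsel <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_burnsel(sprintf("`%s` must be a single finite number", name))
  }
}
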