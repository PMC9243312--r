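#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers behave as pure functions of their
#' arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and one or more indices.
# Splitmix-style integer hash, folded into [0, 2^31 - 2] so it is always a
# valid argument to set.seed() on 32-bit R integers.
derive_seed <- function(seed, ...) {
  v <- as.double(seed)
  for (ix in list(...)) {
    v <- (v * 2654435761 + as.double(ix) * 40503 + 97) %% 2147483647
  }
  as.integer(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("`%s` must be a single finite%s number", name,
                 if (positive) " positive" else ""), call. = FALSE)
  }
  invisible(x)
}
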