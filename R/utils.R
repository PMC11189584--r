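#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random-number stream set to `seed`, restoring
#' the caller's stream afterwards, so that seeded fixture generators do not
#' perturb unrelated randomness. With `seed = NULL` the expression is
#' evaluated as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-up to the nearest integer (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
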