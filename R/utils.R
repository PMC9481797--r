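#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random-number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so seeded helpers never perturb an
#' enclosing simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
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
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("riemeeg_invalid_input", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
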