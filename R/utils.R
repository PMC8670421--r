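#' Evaluate an expression under a local, seeded RNG scope
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state so that seeded package functions never perturb the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("an explicit integer seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

.asCountMatrix <- function(x) {
  if (is(x, "OrfExperiment")) counts(x) else as.matrix(x)
}

# Holm step-down adjustment via stats::p.adjust, kept as a named helper so the
# same family-wise scheme is applied to axis and marginal test families alike.
.holm <- function(p) stats::p.adjust(p, method = "holm")
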