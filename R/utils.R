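#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so that
#' seeded package functions do not perturb the session stream.
#'
#' @param seed Integer seed, or NULL to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
#' @examples
#' withSeed(1, rnorm(2))
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Deterministically spawn child seeds from a master seed
#'
#' One master seed drives every stochastic stage; each stage and each subject
#' receives its own child seed so runs are reproducible and stages are
#' independently replayable.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' spawnSeeds(42, 3)
spawnSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# shared argument checks -----------------------------------------------------

.checkSquareSymmetric <- function(x, what = "matrix") {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(what, " must be a square matrix", call. = FALSE)
  if (!isTRUE(all.equal(x, t(x), tolerance = 1e-8, check.attributes = FALSE)))
    stop(what, " must be symmetric", call. = FALSE)
  invisible(x)
}

.checkMembership <- function(membership, n) {
  if (length(membership) != n)
    stop("partition must cover all ", n, " nodes (got ",
         length(membership), " labels)", call. = FALSE)
  if (anyNA(membership))
    stop("partition contains missing module labels", call. = FALSE)
  invisible(as.integer(membership))
}

# relabel module ids to contiguous 1..K in order of first appearance
.canonicalLabels <- function(membership) {
  as.integer(match(membership, unique(membership)))
}
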