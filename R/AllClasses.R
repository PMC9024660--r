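#' @import methods
NULL

#' Connectome: a node-by-node functional connectivity matrix
#'
#' Square symmetric matrix of pairwise coupling between brain parcels, either
#' Fisher-z transformed Pearson correlations (`kind = "weighted_z"`) or a
#' binary adjacency obtained by proportional thresholding (`kind = "binary"`).
#' The diagonal is exactly zero.
#'
#' @slot values numeric matrix, square and symmetric, zero diagonal.
#' @slot kind character, one of `"weighted_z"` or `"binary"`.
#' @seealso [fisherZConnectome()], [proportionalThreshold()]
#' @export
setClass("Connectome",
         representation(values = "matrix", kind = "character"))

setValidity("Connectome", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v) || nrow(v) != ncol(v))
    msgs <- c(msgs, "values must be a square numeric matrix")
  else {
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8,
                          check.attributes = FALSE)))
      msgs <- c(msgs, "values must be symmetric")
    if (any(diag(v) != 0))
      msgs <- c(msgs, "diagonal must be exactly 0")
    if (identical(object@kind, "binary") && !all(v %in% c(0, 1)))
      msgs <- c(msgs, "binary connectome must contain only 0/1")
  }
  if (!object@kind %in% c("weighted_z", "binary"))
    msgs <- c(msgs, "kind must be 'weighted_z' or 'binary'")
  if (length(msgs)) msgs else TRUE
})

#' ModularPartition: a modular decomposition at one structural resolution
#'
#' Assignment of every node to exactly one module, together with the
#' resolution parameter gamma at which it was obtained and the modularity Q
#' of the assignment. Module labels are contiguous integers starting at 1.
#'
#' @slot gamma numeric, structural resolution (weight on the null model).
#' @slot assignment integer vector, node -> module label.
#' @slot Q numeric, modularity of the assignment.
#' @slot nModules integer, number of distinct modules.
#' @seealso [louvainFinetune()], [gammaSweep()], [consensusPartition()]
#' @export
setClass("ModularPartition",
         representation(gamma = "numeric", assignment = "integer",
                        Q = "numeric", nModules = "integer"))

setValidity("ModularPartition", function(object) {
  msgs <- character()
  a <- object@assignment
  if (anyNA(a)) msgs <- c(msgs, "every node must be assigned a module")
  else {
    labs <- sort(unique(a))
    if (!identical(labs, seq_along(labs)))
      msgs <- c(msgs, "module labels must be contiguous integers from 1")
    if (object@nModules != length(labs))
      msgs <- c(msgs, "nModules must equal the number of distinct labels")
  }
  if (length(object@Q) == 1 && is.finite(object@Q) && object@Q > 1 + 1e-12)
    msgs <- c(msgs, "modularity Q cannot exceed 1")
  if (object@gamma <= 0) msgs <- c(msgs, "gamma must be positive")
  if (length(msgs)) msgs else TRUE
})

#' AgreementMatrix: cross-subject module co-assignment counts
#'
#' Entry (i, j) counts in how many of the contributing partitions nodes i and
#' j were placed in the same module. The diagonal equals the number of
#' partitions. Module-size profiles of the contributing partitions are kept
#' so that the analytic null co-assignment rate under label permutation can
#' be derived without re-access to the partitions.
#'
#' @slot counts integer-valued square symmetric matrix.
#' @slot nPartitions integer, number of partitions tallied.
#' @slot moduleSizes list of integer vectors, module sizes per partition.
#' @seealso [agreementMatrix()], [consensusPartition()]
#' @export
setClass("AgreementMatrix",
         representation(counts = "matrix", nPartitions = "integer",
                        moduleSizes = "list"))

setValidity("AgreementMatrix", function(object) {
  msgs <- character()
  cts <- object@counts
  np <- object@nPartitions
  if (nrow(cts) != ncol(cts)) msgs <- c(msgs, "counts must be square")
  if (any(cts < 0) || any(cts > np))
    msgs <- c(msgs, "counts must lie in [0, nPartitions]")
  if (any(diag(cts) != np))
    msgs <- c(msgs, "diagonal must equal nPartitions")
  if (!isTRUE(all.equal(cts, t(cts), check.attributes = FALSE)))
    msgs <- c(msgs, "counts must be symmetric")
  if (length(msgs)) msgs else TRUE
})

# constructors ---------------------------------------------------------------

#' Construct a Connectome
#'
#' @param values square symmetric numeric matrix with zero diagonal.
#' @param kind `"weighted_z"` or `"binary"`.
#' @return A [Connectome-class] object.
#' @export
Connectome <- function(values, kind = c("weighted_z", "binary")) {
  kind <- match.arg(kind)
  new("Connectome", values = unname(as.matrix(values)), kind = kind)
}

#' Construct a ModularPartition
#'
#' Labels are canonicalised to contiguous integers starting at 1, in order of
#' first appearance.
#'
#' @param assignment vector of module labels, one per node.
#' @param gamma structural resolution at which the partition was obtained.
#' @param Q modularity of the assignment (computed by callers).
#' @return A [ModularPartition-class] object.
#' @export
ModularPartition <- function(assignment, gamma = 1, Q = NA_real_) {
  a <- .canonicalLabels(assignment)
  new("ModularPartition", gamma = as.numeric(gamma), assignment = a,
      Q = as.numeric(Q), nModules = length(unique(a)))
}

# accessors ------------------------------------------------------------------

#' @describeIn Connectome-class number of nodes
#' @param x a Connectome, ModularPartition or AgreementMatrix.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @export
setMethod("nNodes", "Connectome", function(x) nrow(x@values))

#' @export
setMethod("nNodes", "ModularPartition", function(x) length(x@assignment))

#' @export
setMethod("nNodes", "AgreementMatrix", function(x) nrow(x@counts))

#' Matrix of connectivity values
#' @param x a Connectome.
#' @return numeric matrix.
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @export
setMethod("connValues", "Connectome", function(x) x@values)

#' Kind of connectome ("weighted_z" or "binary")
#' @param x a Connectome.
#' @export
setGeneric("connKind", function(x) standardGeneric("connKind"))

#' @export
setMethod("connKind", "Connectome", function(x) x@kind)

#' Module assignment vector of a partition
#' @param x a ModularPartition.
#' @return integer vector of module labels (1-based, contiguous).
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' @export
setMethod("moduleAssignment", "ModularPartition", function(x) x@assignment)

#' Modularity Q of a partition
#' @param x a ModularPartition.
#' @export
setGeneric("modularityValue", function(x) standardGeneric("modularityValue"))

#' @export
setMethod("modularityValue", "ModularPartition", function(x) x@Q)

#' Structural resolution gamma of a partition
#' @param x a ModularPartition.
#' @export
setGeneric("gammaValue", function(x) standardGeneric("gammaValue"))

#' @export
setMethod("gammaValue", "ModularPartition", function(x) x@gamma)

#' Number of modules in a partition
#' @param x a ModularPartition.
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @export
setMethod("nModules", "ModularPartition", function(x) x@nModules)

#' Co-assignment counts of an agreement matrix
#' @param x an AgreementMatrix.
#' @export
setGeneric("agreementCounts", function(x) standardGeneric("agreementCounts"))

#' @export
setMethod("agreementCounts", "AgreementMatrix", function(x) x@counts)

#' Number of partitions tallied in an agreement matrix
#' @param x an AgreementMatrix.
#' @export
setGeneric("nPartitions", function(x) standardGeneric("nPartitions"))

#' @export
setMethod("nPartitions", "AgreementMatrix", function(x) x@nPartitions)

# show methods ---------------------------------------------------------------

setMethod("show", "Connectome", function(object) {
  v <- object@values
  dens <- if (object@kind == "binary")
    sum(v[upper.tri(v)]) / (nrow(v) * (nrow(v) - 1) / 2) else NA
  cat(sprintf("Connectome (%s): %d nodes", object@kind, nrow(v)))
  if (!is.na(dens)) cat(sprintf(", density %.3f", dens))
  cat("\n")
})

setMethod("show", "ModularPartition", function(object) {
  cat(sprintf(
    "ModularPartition: %d nodes, %d modules, gamma = %.2f, Q = %.4f\n",
    length(object@assignment), object@nModules, object@gamma, object@Q))
})

setMethod("show", "AgreementMatrix", function(object) {
  cat(sprintf("AgreementMatrix: %d nodes, %d partitions\n",
              nrow(object@counts), object@nPartitions))
})
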