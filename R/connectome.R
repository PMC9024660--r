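#' Fisher-z correlation connectome from nodal time series
#'
#' Computes the Pearson correlation between every pair of nodal time series
#' and applies the Fisher z transform (atanh). Correlations with magnitude at
#' or above `1 - eps` are capped at `atanh(1 - eps)` so perfectly (anti-)
#' correlated pairs stay finite; a warning reports how many pairs were
#' capped. The diagonal is forced to zero.
#'
#' @param timeseries numeric matrix, nodes in rows, time points in columns.
#' @param eps cap tolerance; correlations with `|r| >= 1 - eps` are clipped.
#' @return A [Connectome-class] of kind `"weighted_z"`.
#' @export
#' @examples
#' ts <- matrix(rnorm(5 * 50), nrow = 5)
#' fisherZConnectome(ts)
fisherZConnectome <- function(timeseries, eps = 1e-7) {
  ts <- as.matrix(timeseries)
  if (ncol(ts) < 3)
    stop("need at least 3 time points, got ", ncol(ts), call. = FALSE)
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("constant time series at node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(ts))
  diag(r) <- 0
  over <- abs(r) >= 1 - eps
  if (any(over)) {
    warning(sum(over[upper.tri(over)]),
            " node pair(s) with |r| >= 1 - eps capped before atanh")
    r[over] <- sign(r[over]) * (1 - eps)
  }
  z <- atanh(r)
  diag(z) <- 0
  Connectome((z + t(z)) / 2, kind = "weighted_z")
}

#' Binarize a weighted connectome by proportional thresholding
#'
#' Keeps exactly `floor(density * n * (n - 1) / 2)` upper-triangle edges —
#' the strongest by signed z value (or by absolute value with
#' `rank = "absolute"`) — and sets them to 1, mirroring to symmetry. Ties at
#' the cutoff are broken deterministically in lexicographic (row, column)
#' order. The retained edge count depends only on `n` and `density`, so it
#' is identical for every subject of a cohort, holding network density fixed
#' across individuals.
#'
#' @param conn a weighted [Connectome-class] (or bare symmetric matrix).
#' @param density fraction of possible edges to retain, in (0, 1].
#' @param rank `"signed"` (default: largest positive correlations) or
#'   `"absolute"` (largest magnitudes regardless of sign).
#' @return A binary [Connectome-class].
#' @export
#' @examples
#' z <- fisherZConnectome(matrix(rnorm(10 * 80), nrow = 10))
#' b <- proportionalThreshold(z, density = 0.10)
#' sum(connValues(b)) / 2  # retained edges
proportionalThreshold <- function(conn, density = 0.10,
                                  rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  w <- if (is(conn, "Connectome")) conn@values else
    .checkSquareSymmetric(as.matrix(conn), "connectome")
  n <- nrow(w)
  if (density <= 0 || density > 1)
    stop("density must be in (0, 1]", call. = FALSE)
  nPossible <- n * (n - 1) / 2
  nKeep <- floor(density * nPossible)
  if (nKeep < 1)
    stop("density ", density, " retains zero edges on ", n, " nodes",
         call. = FALSE)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[ut]
  if (rank == "absolute") vals <- abs(vals)
  # stable ordering: decreasing value, then lexicographic (i, j)
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(nKeep)]
  adj <- matrix(0, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  Connectome(adj, kind = "binary")
}

#' Assemble a node registry for the parcellation
#'
#' Builds the bookkeeping table of graph nodes: contiguous ids, labels, the
#' atlas component each parcel belongs to (cortical, subcortical,
#' cerebellar), and MNI coordinates. Defaults reproduce the 418-node
#' parcellation used throughout the package (346 cortical + 40 subcortical +
#' 32 cerebellar). The coordinates generated here are synthetic placeholders
#' scattered within plausible component-specific bounding boxes — suitable
#' for bookkeeping and plotting demos, not for anatomical claims; supply a
#' real registry via [readNodeRegistry()] when available.
#'
#' @param nCortical,nSubcortical,nCerebellar nodes per atlas component.
#' @param seed seed for the placeholder coordinates.
#' @return data.frame with columns `node_id` (0-based, contiguous), `label`,
#'   `component`, `x`, `y`, `z`.
#' @export
#' @examples
#' nrow(makeNodeRegistry())  # 418
makeNodeRegistry <- function(nCortical = 346, nSubcortical = 40,
                             nCerebellar = 32, seed = 1L) {
  comp <- rep(c("cortical", "subcortical", "cerebellar"),
              c(nCortical, nSubcortical, nCerebellar))
  n <- length(comp)
  boxes <- list(cortical     = rbind(c(-70, 70), c(-100, 70), c(-45, 75)),
                subcortical  = rbind(c(-35, 35), c(-40, 25), c(-20, 25)),
                cerebellar   = rbind(c(-50, 50), c(-85, -40), c(-60, -10)))
  withSeed(seed, {
    xyz <- t(vapply(comp, function(cc) {
      b <- boxes[[cc]]
      stats::runif(3, b[, 1], b[, 2])
    }, numeric(3)))
  })
  data.frame(node_id = seq_len(n) - 1L,
             label = sprintf("%s_%03d", substr(comp, 1, 4),
                             stats::ave(seq_len(n), comp, FUN = seq_along)),
             component = comp,
             x = round(xyz[, 1], 1), y = round(xyz[, 2], 1),
             z = round(xyz[, 3], 1),
             row.names = NULL)
}

# I/O ------------------------------------------------------------------------

#' Read a delimited node-by-time series matrix
#'
#' @param path file with one row per node, columns = time points.
#' @param sep field separator.
#' @return numeric matrix (nodes x time).
#' @export
readTimeSeries <- function(path, sep = ",") {
  as.matrix(utils::read.table(path, sep = sep, header = FALSE))
}

#' Read a delimited square connectivity matrix
#'
#' @param path file holding a square delimited matrix.
#' @param kind `"weighted_z"` or `"binary"`.
#' @param sep field separator.
#' @return A [Connectome-class].
#' @export
readConnectome <- function(path, kind = c("weighted_z", "binary"),
                           sep = ",") {
  kind <- match.arg(kind)
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  Connectome(m, kind = kind)
}

#' Write a connectome as a delimited square matrix
#'
#' @param conn a [Connectome-class].
#' @param path output file.
#' @param sep field separator.
#' @export
writeConnectome <- function(conn, path, sep = ",") {
  utils::write.table(connValues(conn), path, sep = sep,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a node registry CSV
#'
#' Expects a header with columns `node_id,label,component,x,y,z`; node ids
#' must be unique and contiguous from 0.
#'
#' @param path CSV file.
#' @return data.frame registry.
#' @export
readNodeRegistry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "label", "component", "x", "y", "z")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("node registry missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- sort(reg$node_id)
  if (anyDuplicated(ids) || !identical(as.integer(ids),
                                       seq_len(nrow(reg)) - 1L))
    stop("node ids must be unique and contiguous from 0", call. = FALSE)
  reg
}
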