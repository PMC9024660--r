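#' @importFrom igraph graph_from_adjacency_matrix betweenness distances
NULL

.asAdjacency <- function(x) {
  a <- if (is(x, "Connectome")) x@values else as.matrix(x)
  .checkSquareSymmetric(a, "adjacency")
  if (!all(a %in% c(0, 1)))
    stop("adjacency must be binary (0/1); threshold the connectome first",
         call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency diagonal must be 0", call. = FALSE)
  unname(a)
}

.asIgraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Degree centrality
#'
#' Number of links attached to each node of a binary undirected graph.
#'
#' @param adj binary symmetric adjacency matrix (or binary
#'   [Connectome-class]).
#' @return numeric vector, one value per node.
#' @export
nodeDegree <- function(adj) {
  a <- .asAdjacency(adj)
  rowSums(a)
}

#' Betweenness centrality
#'
#' For each node v, the sum over unordered pairs (s, t), s != t != v, of the
#' fraction of shortest s-t paths passing through v (unit edge lengths).
#' Returned unnormalized by default; pairs in different components contribute
#' zero.
#'
#' @param adj binary symmetric adjacency matrix or binary Connectome.
#' @param normalized divide by the number of pairs `(n-1)(n-2)/2`.
#' @return numeric vector of path-fraction sums per node.
#' @export
nodeBetweenness <- function(adj, normalized = FALSE) {
  a <- .asAdjacency(adj)
  b <- igraph::betweenness(.asIgraph(a), directed = FALSE, normalized = FALSE)
  b <- unname(b)
  if (normalized) {
    n <- nrow(a)
    if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  }
  b
}

#' Closeness centrality (Wasserman-Faust composite)
#'
#' Handles disconnected graphs deterministically: with `r_v` the number of
#' nodes reachable from v (excluding v) and `d(v, u)` geodesic distances,
#' closeness is `(r_v / (n - 1)) * (r_v / sum of d(v, u) over reachable u)`.
#' On a connected graph this reduces to the classical inverse farness scaled
#' to 1 for a node adjacent to all others. Isolated nodes score 0.
#'
#' @param adj binary symmetric adjacency matrix or binary Connectome.
#' @return numeric vector per node, in [0, 1].
#' @export
nodeCloseness <- function(adj) {
  a <- .asAdjacency(adj)
  n <- nrow(a)
  if (n == 1) return(0)
  d <- igraph::distances(.asIgraph(a))
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- is.finite(dv)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(dv[reach]))
  }, numeric(1))
}

#' Participation coefficient
#'
#' Extent of intermodular connectivity of each node given a module
#' partition: `P_v = 1 - sum_s (k_vs / k_v)^2`, where `k_vs` counts edges
#' from v into module s. Zero for nodes whose edges all stay within one
#' module; approaches 1 as edges spread evenly over many modules.
#' Disconnected nodes (`k_v = 0`) are assigned 0.
#'
#' @param adj binary symmetric adjacency matrix or binary Connectome.
#' @param membership module label per node (vector, or
#'   [ModularPartition-class]).
#' @return numeric vector per node, in [0, 1).
#' @export
participationCoef <- function(adj, membership) {
  a <- .asAdjacency(adj)
  m <- if (is(membership, "ModularPartition"))
    membership@assignment else membership
  m <- .checkMembership(m, nrow(a))
  k <- rowSums(a)
  mods <- sort(unique(m))
  # k_vs: node-by-module edge counts
  kvs <- vapply(mods, function(s) rowSums(a[, m == s, drop = FALSE]),
                numeric(nrow(a)))
  p <- 1 - rowSums((kvs / pmax(k, 1))^2)
  p[k == 0] <- 0
  unname(p)
}

#' Within-module degree
#'
#' Intra-modular connectivity of each node: its number of links to nodes of
#' its own module, z-scored within the module (population standard
#' deviation). Modules whose members all share the same within-degree (e.g.
#' cliques) get z = 0 throughout. Set `zscore = FALSE` for the raw
#' within-module link counts.
#'
#' @param adj binary symmetric adjacency matrix or binary Connectome.
#' @param membership module label per node (vector or ModularPartition).
#' @param zscore z-score within modules (default) or return raw counts.
#' @return numeric vector per node.
#' @export
withinModuleDegree <- function(adj, membership, zscore = TRUE) {
  a <- .asAdjacency(adj)
  m <- if (is(membership, "ModularPartition"))
    membership@assignment else membership
  m <- .checkMembership(m, nrow(a))
  kappa <- vapply(seq_len(nrow(a)), function(v)
    sum(a[v, m == m[v]]), numeric(1))
  if (!zscore) return(kappa)
  z <- numeric(length(kappa))
  for (s in unique(m)) {
    idx <- which(m == s)
    mu <- mean(kappa[idx])
    sdp <- sqrt(mean((kappa[idx] - mu)^2))  # population SD
    z[idx] <- if (sdp == 0) 0 else (kappa[idx] - mu) / sdp
  }
  z
}

#' All five nodal topology metrics for one graph
#'
#' Computes degree, betweenness, closeness, participation coefficient and
#' within-module degree z for a binary graph under a module partition, in a
#' tidy long table.
#'
#' @param adj binary symmetric adjacency matrix or binary Connectome.
#' @param membership module labels (vector or ModularPartition).
#' @param subject_id identifier copied into the table.
#' @param gamma structural resolution the partition belongs to.
#' @return data.frame with columns
#'   `subject_id, node_id, gamma, metric, value`; `node_id` is 0-based to
#'   match the node registry. Metrics are named `degree`, `betweenness`,
#'   `closeness`, `participation`, `within_module_degree`.
#' @export
nodalMetrics <- function(adj, membership, subject_id = "S1", gamma = 1) {
  a <- .asAdjacency(adj)
  n <- nrow(a)
  vals <- list(degree = nodeDegree(a),
               betweenness = nodeBetweenness(a),
               closeness = nodeCloseness(a),
               participation = participationCoef(a, membership),
               within_module_degree = withinModuleDegree(a, membership))
  data.frame(subject_id = subject_id,
             node_id = rep(seq_len(n) - 1L, times = 5L),
             gamma = gamma,
             metric = rep(names(vals), each = n),
             value = unlist(vals, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Write / read a tidy nodal metric table
#'
#' Long format with columns `subject_id,node_id,gamma,metric,value`.
#'
#' @param x metric table data.frame.
#' @param path CSV path.
#' @export
writeMetricTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricTable
#' @export
readMetricTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
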