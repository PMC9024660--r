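#' @importFrom igraph rewire keeping_degseq
NULL

# modularity of a (possibly weighted) symmetric matrix under a membership
# vector; m2 = total weight = sum(W) (both ordered pairs)
.modularityW <- function(W, membership, gamma) {
  m2 <- sum(W)
  k <- rowSums(W)
  same <- outer(membership, membership, "==")
  (sum(W[same]) - gamma * sum(outer(k, k)[same]) / m2) / m2
}

#' Modularity Q of a partition
#'
#' `Q = (1/2m) * sum_ij [A_ij - gamma * k_i * k_j / (2m)] * delta(c_i, c_j)`
#' with `m` the total edge weight and gamma the structural resolution that
#' weights the configuration-model null. Accepts binary or non-negative
#' weighted symmetric matrices.
#'
#' @param adj symmetric adjacency / weight matrix or binary Connectome.
#' @param membership module labels (vector or [ModularPartition-class]).
#' @param gamma structural resolution (> 0).
#' @return numeric Q (at most 1).
#' @export
#' @examples
#' a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1
#' modularityQ(a, c(1, 1, 2, 2))  # 0.5
modularityQ <- function(adj, membership, gamma = 1) {
  W <- if (is(adj, "Connectome")) adj@values else
    .checkSquareSymmetric(as.matrix(adj), "adjacency")
  m <- if (is(membership, "ModularPartition"))
    membership@assignment else membership
  m <- .checkMembership(m, nrow(W))
  if (sum(W) == 0) stop("graph has no edges; modularity undefined",
                        call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  .modularityW(W, m, gamma)
}

# one sweep of local moves (repeated until no move improves Q), starting
# from `comm`; nodes are visited in randomised order each pass
.louvainLevel <- function(W, gamma, comm) {
  n <- nrow(W)
  m2 <- sum(W)
  s <- rowSums(W)
  sigma <- numeric(max(comm))
  agg <- rowsum(s, comm)
  sigma[as.integer(rownames(agg))] <- agg
  movedAny <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      a <- comm[i]
      wi <- W[i, ]
      nb <- which(wi > 0)
      nb <- nb[nb != i]
      if (!length(nb)) next
      kic <- rowsum(wi[nb], comm[nb])
      cand <- as.integer(rownames(kic))
      kic <- kic[, 1]
      sigmaEx <- sigma[cand]
      sigmaEx[cand == a] <- sigmaEx[cand == a] - s[i]
      fit <- kic - gamma * s[i] * sigmaEx / m2
      fa <- if (a %in% cand) fit[cand == a] else -gamma * s[i] *
        (sigma[a] - s[i]) / m2
      best <- which.max(fit)
      if (cand[best] != a && fit[best] > fa + 1e-12) {
        sigma[a] <- sigma[a] - s[i]
        sigma[cand[best]] <- sigma[cand[best]] + s[i]
        comm[i] <- cand[best]
        moved <- TRUE
      }
    }
    if (!moved) break
    movedAny <- TRUE
  }
  list(comm = comm, moved = movedAny)
}

# full Louvain (local moves + aggregation, recursively) from an optional
# initial membership; returns the membership of the original nodes
.louvain <- function(W, gamma, init = NULL) {
  n0 <- nrow(W)
  assign0 <- seq_len(n0)
  comm <- if (is.null(init)) seq_len(n0) else .canonicalLabels(init)
  Wcur <- W
  repeat {
    lev <- .louvainLevel(Wcur, gamma, comm)
    comm <- .canonicalLabels(lev$comm)
    assign0 <- comm[assign0]
    k <- max(comm)
    if (!lev$moved || k == nrow(Wcur)) break
    # aggregate communities into super-nodes (self-loops keep internal weight)
    Wcur <- rowsum(t(rowsum(Wcur, comm)), comm)
    comm <- seq_len(k)
  }
  assign0
}

#' Louvain community detection with iterated fine-tuning
#'
#' Detects the optimal modular architecture of one graph at resolution gamma.
#' Each cycle starts every node in the community found by the previous cycle
#' (initially: all singletons), runs the Louvain algorithm (randomised node
#' order per pass, greedy local moves, aggregation), and measures modularity
#' Q; cycles repeat until Q can no longer be incremented (improvement below
#' `tol`). Q is non-decreasing over cycles by construction. Deterministic
#' given `seed`.
#'
#' @param adj binary or non-negative weighted symmetric matrix, or a binary
#'   [Connectome-class].
#' @param gamma structural resolution (> 0); larger values favour more,
#'   smaller modules.
#' @param seed integer seed for the randomised node orderings.
#' @param tol stop when a fine-tuning cycle improves Q by less than this.
#' @param maxCycles hard cap on fine-tuning cycles.
#' @return A [ModularPartition-class] with the final assignment and Q.
#' @export
#' @examples
#' a <- kronecker(diag(2), matrix(1, 5, 5)); diag(a) <- 0  # two K5s
#' p <- louvainFinetune(a, gamma = 1, seed = 1)
#' modularityValue(p)  # 0.5
louvainFinetune <- function(adj, gamma = 1, seed = 1L, tol = 1e-10,
                            maxCycles = 100L) {
  W <- if (is(adj, "Connectome")) adj@values else
    .checkSquareSymmetric(as.matrix(adj), "adjacency")
  if (any(W < 0)) stop("negative weights are not supported", call. = FALSE)
  if (sum(W) == 0) stop("graph has no edges", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  withSeed(seed, {
    comm <- .louvain(W, gamma)
    q <- .modularityW(W, comm, gamma)
    for (cycle in seq_len(maxCycles)) {
      comm2 <- .louvain(W, gamma, init = comm)
      q2 <- .modularityW(W, comm2, gamma)
      if (q2 > q) {
        comm <- comm2
        dq <- q2 - q
        q <- q2
        if (dq < tol) break
      } else break
    }
    ModularPartition(comm, gamma = gamma, Q = q)
  })
}

#' Optimal partitions across a sweep of structural resolutions
#'
#' Runs [louvainFinetune()] at every gamma of a strictly increasing grid
#' (default 0.3 to 5.0 in steps of 0.1, i.e. 48 resolutions) and returns one
#' partition per gamma. Each gamma gets its own child seed spawned from
#' `seed`.
#'
#' @param adj graph as in [louvainFinetune()].
#' @param gammas strictly increasing vector of resolutions.
#' @param seed master seed.
#' @return named list of [ModularPartition-class], names = gamma values.
#' @export
gammaSweep <- function(adj, gammas = seq(0.3, 5.0, by = 0.1), seed = 1L) {
  if (any(diff(gammas) <= 0))
    stop("gamma grid must be strictly increasing", call. = FALSE)
  seeds <- spawnSeeds(seed, length(gammas))
  out <- Map(function(g, s) louvainFinetune(adj, gamma = g, seed = s),
             gammas, seeds)
  names(out) <- formatC(gammas, format = "fg")
  out
}

#' Tidy table of modularity values from sweep results
#'
#' @param sweeps named list of per-subject gamma sweeps (each a list of
#'   [ModularPartition-class] as returned by [gammaSweep()]).
#' @return data.frame `subject_id, gamma, Q, n_modules`.
#' @export
modularityTable <- function(sweeps) {
  do.call(rbind, lapply(names(sweeps), function(sid) {
    parts <- sweeps[[sid]]
    data.frame(subject_id = sid,
               gamma = vapply(parts, gammaValue, numeric(1)),
               Q = vapply(parts, modularityValue, numeric(1)),
               n_modules = vapply(parts, nModules, integer(1)),
               row.names = NULL)
  }))
}

#' Cross-subject agreement matrix
#'
#' Counts, for every node pair, in how many of the supplied partitions the
#' two nodes share a module. All partitions must cover the same node set.
#'
#' @param partitions list of [ModularPartition-class] (or membership
#'   vectors), typically one per subject at a fixed gamma.
#' @return An [AgreementMatrix-class].
#' @export
agreementMatrix <- function(partitions) {
  ms <- lapply(partitions, function(p)
    if (is(p, "ModularPartition")) p@assignment else as.integer(p))
  ns <- vapply(ms, length, integer(1))
  if (length(unique(ns)) != 1)
    stop("partitions cover different node sets (sizes: ",
         paste(unique(ns), collapse = ", "), ")", call. = FALSE)
  n <- ns[1]
  cts <- matrix(0L, n, n)
  for (m in ms) cts <- cts + outer(m, m, "==")
  new("AgreementMatrix", counts = cts, nPartitions = length(ms),
      moduleSizes = lapply(ms, function(m) as.integer(table(m))))
}

# expected co-assignment proportion of a random node pair if every
# partition's labels were permuted over nodes (module-size profile kept)
.nullAgreementRate <- function(agree) {
  n <- nNodes(agree)
  rates <- vapply(agree@moduleSizes, function(sz)
    sum(sz * (sz - 1)) / (n * (n - 1)), numeric(1))
  mean(rates)
}

#' Group-level consensus partition from an agreement matrix
#'
#' Iterative consensus clustering: the co-assignment counts are normalised to
#' proportions, entries at or below the analytic null co-assignment rate
#' (expected under node-label permutation of each contributing partition,
#' given its module-size profile) are zeroed, and the thresholded matrix is
#' re-clustered with `reps` seeded runs of [louvainFinetune()]. If the runs
#' disagree, their own agreement matrix feeds the next iteration; the
#' procedure stops when the partition is reproduced identically by every run
#' (block-constant agreement), returning the run with the highest consensus
#' modularity.
#'
#' @param agree An [AgreementMatrix-class].
#' @param reps number of seeded clustering restarts per iteration.
#' @param seed master seed.
#' @param gamma resolution label recorded on the result (the resolution the
#'   contributing subject partitions were obtained at); the re-clustering of
#'   the consensus matrix itself uses `consensusGamma`.
#' @param consensusGamma resolution for re-clustering the agreement structure.
#' @param maxIter maximum consensus iterations before aborting.
#' @return A [ModularPartition-class]; its Q slot holds the modularity of the
#'   final partition on the thresholded consensus matrix.
#' @export
consensusPartition <- function(agree, reps = 1000L, seed = 1L, gamma = 1,
                               consensusGamma = 1, maxIter = 50L) {
  stopifnot(is(agree, "AgreementMatrix"))
  P <- agree@counts / agree@nPartitions
  tau <- .nullAgreementRate(agree)
  n <- nrow(P)
  iterSeeds <- spawnSeeds(seed, maxIter)
  for (iter in seq_len(maxIter)) {
    D <- P
    D[D <= tau] <- 0
    diag(D) <- 0
    if (sum(D) == 0)
      stop("consensus failed: no co-assignment above the null rate (",
           signif(tau, 3), ") at iteration ", iter, call. = FALSE)
    runSeeds <- spawnSeeds(iterSeeds[iter], reps)
    runs <- lapply(runSeeds, function(s)
      louvainFinetune(D, gamma = consensusGamma, seed = s))
    qs <- vapply(runs, modularityValue, numeric(1))
    ms <- vapply(runs, moduleAssignment, integer(n))
    if (reps == 1L || all(apply(ms, 1, function(r) length(unique(r)) == 1))) {
      best <- runs[[which.max(qs)]]
      return(ModularPartition(best@assignment, gamma = gamma,
                              Q = best@Q))
    }
    nxt <- agreementMatrix(lapply(seq_len(ncol(ms)), function(j) ms[, j]))
    P <- nxt@counts / nxt@nPartitions
    tau <- .nullAgreementRate(nxt)
  }
  stop("consensus clustering did not converge in ", maxIter,
       " iterations (last null rate ", signif(tau, 3), ", ",
       reps, " runs per iteration)", call. = FALSE)
}

#' Permutation screen for significant consensus modules
#'
#' Tests each module of a group-level consensus partition against chance:
#' the observed statistic is the module's mean within-module agreement
#' proportion; the null distribution rebuilds the agreement matrix after
#' randomly permuting the node labels of every subject partition. A module is
#' kept when its observed agreement exceeds the 95th percentile (by default)
#' of its null.
#'
#' @param consensus A [ModularPartition-class] (group-level).
#' @param partitions the subject partitions the agreement was built from.
#' @param nNull number of permutation replicates.
#' @param seed seed for the permutations.
#' @param level null quantile a module must exceed to be kept.
#' @return data.frame `module, size, observed, null_crit, keep`.
#' @export
moduleSignificance <- function(consensus, partitions, nNull = 100L,
                               seed = 1L, level = 0.95) {
  ms <- lapply(partitions, function(p)
    if (is(p, "ModularPartition")) p@assignment else as.integer(p))
  n <- length(ms[[1]])
  cons <- moduleAssignment(consensus)
  mods <- sort(unique(cons))
  if (length(mods) == 1)
    warning("single-module consensus partition: kept vacuously")
  P <- agreementMatrix(ms)@counts / length(ms)
  moduleMean <- function(Pm, nodes) {
    if (length(nodes) < 2) return(NA_real_)
    sub <- Pm[nodes, nodes]
    mean(sub[upper.tri(sub)])
  }
  obs <- vapply(mods, function(s) moduleMean(P, which(cons == s)),
                numeric(1))
  nullMat <- withSeed(seed, {
    vapply(seq_len(nNull), function(rep) {
      perm <- lapply(ms, function(m) m[sample.int(n)])
      Pn <- agreementMatrix(perm)@counts / length(ms)
      vapply(mods, function(s) moduleMean(Pn, which(cons == s)), numeric(1))
    }, numeric(length(mods)))
  })
  nullMat <- matrix(nullMat, nrow = length(mods))
  crit <- apply(nullMat, 1, stats::quantile, probs = level, na.rm = TRUE,
                names = FALSE)
  keep <- ifelse(is.na(obs), TRUE, obs > crit)
  if (length(mods) == 1) keep[] <- TRUE
  data.frame(module = mods,
             size = as.integer(table(factor(cons, levels = mods))),
             observed = obs, null_crit = crit, keep = keep)
}

#' Correlation between subject modularity and a trait across resolutions
#'
#' Pearson correlation between per-subject modularity Q and a trait score at
#' every gamma, summarised by the cross-gamma mean and SD — a test of
#' "global" trait encoding in the connectome. Resolutions where Q has zero
#' variance are excluded with a warning.
#'
#' @param qTable data.frame `subject_id, gamma, Q` ([modularityTable()]).
#' @param traits named numeric vector of trait scores (names = subject ids).
#' @return list with `per_gamma` (data.frame `gamma, r, n`), `mean_r`,
#'   `sd_r`.
#' @export
modularityTraitCorrelation <- function(qTable, traits) {
  gs <- sort(unique(qTable$gamma))
  rows <- lapply(gs, function(g) {
    sub <- qTable[qTable$gamma == g, ]
    tr <- traits[as.character(sub$subject_id)]
    ok <- stats::complete.cases(sub$Q, tr)
    if (stats::sd(sub$Q[ok]) == 0 || stats::sd(tr[ok]) == 0) {
      warning("zero variance at gamma = ", g, "; excluded")
      return(NULL)
    }
    data.frame(gamma = g, r = stats::cor(sub$Q[ok], tr[ok]), n = sum(ok))
  })
  per <- do.call(rbind, rows)
  list(per_gamma = per, mean_r = mean(per$r), sd_r = stats::sd(per$r))
}

#' Null-adjusted modularity (optional diagnostic)
#'
#' z-scores the optimised modularity of a graph against degree-preserving
#' rewired null graphs, each re-optimised at the same resolution. This is an
#' optional diagnostic for comparing modularity across graphs with different
#' degree structure; it feeds no downstream stage.
#'
#' @param adj binary symmetric adjacency or binary Connectome.
#' @param gamma structural resolution.
#' @param nNull number of rewired null graphs.
#' @param seed seed.
#' @return list `q_obs, null_mean, null_sd, z`.
#' @export
adjustedModularity <- function(adj, gamma = 1, nNull = 50L, seed = 1L) {
  a <- .asAdjacency(adj)
  seeds <- spawnSeeds(seed, nNull + 1L)
  qObs <- modularityValue(louvainFinetune(a, gamma, seed = seeds[1]))
  g <- .asIgraph(a)
  nEdge <- sum(a) / 2
  qNull <- withSeed(seed, vapply(seq_len(nNull), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * nEdge))
    an <- as.matrix(igraph::as_adjacency_matrix(gr))
    modularityValue(louvainFinetune(an, gamma, seed = seeds[i + 1L]))
  }, numeric(1)))
  list(q_obs = qObs, null_mean = mean(qNull), null_sd = stats::sd(qNull),
       z = (qObs - mean(qNull)) / stats::sd(qNull))
}

#' Write / read a partition as two-column CSV
#'
#' Gamma and Q travel in `#`-prefixed header comments.
#'
#' @param partition A [ModularPartition-class].
#' @param path CSV path.
#' @export
writePartition <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gamma=%.10g", gammaValue(partition)), con)
  writeLines(sprintf("# Q=%.10g", modularityValue(partition)), con)
  writeLines("node_id,module_label", con)
  a <- moduleAssignment(partition)
  writeLines(sprintf("%d,%d", seq_along(a) - 1L, a), con)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  g <- as.numeric(sub("^# gamma=", "", grep("gamma=", hdr, value = TRUE)))
  q <- as.numeric(sub("^# Q=", "", grep("Q=", hdr, value = TRUE)))
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  ord <- order(body$node_id)
  ModularPartition(body$module_label[ord], gamma = g, Q = q)
}

#' Write an agreement matrix as a delimited square table
#'
#' @param agree An [AgreementMatrix-class].
#' @param path output path.
#' @export
writeAgreement <- function(agree, path) {
  utils::write.table(agreementCounts(agree), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
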