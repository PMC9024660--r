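# Brute-force oracles for the five nodal metrics, written independently of
# the package implementation: distances by iterative neighbour expansion,
# betweenness by exhaustive enumeration of all shortest paths (feasible for
# the <= 8-node graphs used in the oracle tests).

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < p)
  a + t(a)
}

# shortest-path distances by breadth-first frontier expansion
bruteDistances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) > 0
  frontier <- reach
  step <- 0
  while (any(frontier)) {
    step <- step + 1
    nxt <- (frontier %*% a) > 0 & !reach
    d[nxt] <- step
    reach <- reach | nxt
    frontier <- nxt
  }
  d
}

# enumerate every shortest s-t path (as node sequences) by depth-first
# search constrained to the distance structure
allShortestPaths <- function(a, d, s, t) {
  paths <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (u in which(a[v, ] == 1)) {
      if (d[s, u] == d[s, v] + 1 && d[u, t] == d[v, t] - 1) {
        recurse(c(path, u))
      }
    }
  }
  if (is.finite(d[s, t])) recurse(s)
  paths
}

bruteBetweenness <- function(a) {
  n <- nrow(a)
  d <- bruteDistances(a)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- allShortestPaths(a, d, s, t)
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      b[idx] <- b[idx] + as.numeric(tab) / length(paths)
    }
  }
  b
}

bruteDegree <- function(a) {
  # tally over an explicit edge list
  el <- which(a == 1, arr.ind = TRUE)
  el <- el[el[, 1] < el[, 2], , drop = FALSE]
  deg <- numeric(nrow(a))
  for (r in seq_len(nrow(el))) {
    deg[el[r, 1]] <- deg[el[r, 1]] + 1
    deg[el[r, 2]] <- deg[el[r, 2]] + 1
  }
  deg
}

bruteCloseness <- function(a) {
  n <- nrow(a)
  d <- bruteDistances(a)
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    r <- sum(is.finite(dv))
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(dv[is.finite(dv)]))
  }, numeric(1))
}

bruteParticipation <- function(a, m) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    kv <- sum(a[v, ])
    if (kv == 0) return(0)
    1 - sum(vapply(unique(m), function(s)
      (sum(a[v, m == s]) / kv)^2, numeric(1)))
  }, numeric(1))
}

bruteWithinModuleDegree <- function(a, m) {
  n <- nrow(a)
  kappa <- vapply(seq_len(n), function(v) sum(a[v, m == m[v]]), numeric(1))
  z <- numeric(n)
  for (s in unique(m)) {
    idx <- which(m == s)
    mu <- mean(kappa[idx])
    sdp <- sqrt(sum((kappa[idx] - mu)^2) / length(idx))
    z[idx] <- if (sdp == 0) 0 else (kappa[idx] - mu) / sdp
  }
  z
}

# graph fixtures --------------------------------------------------------------

starGraph <- function(nLeaves = 4) {
  a <- matrix(0, nLeaves + 1, nLeaves + 1)
  a[1, -1] <- a[-1, 1] <- 1
  a
}

completeGraph <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

pathGraph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

# k cliques of `size` nodes arranged in a ring (one edge between
# consecutive cliques)
ringOfCliques <- function(k, size) {
  n <- k * size
  a <- matrix(0, n, n)
  for (b in seq_len(k) - 1) {
    idx <- b * size + seq_len(size)
    a[idx, idx] <- 1
  }
  diag(a) <- 0
  for (b in seq_len(k) - 1) {
    i <- b * size + size
    j <- ((b + 1) %% k) * size + 1
    a[i, j] <- a[j, i] <- 1
  }
  a
}

twoCliques <- function(size = 5) {
  a <- kronecker(diag(2), matrix(1, size, size))
  diag(a) <- 0
  a
}

# a degree-only metric table for fast association simulations
degreeMetricTable <- function(cfg, cohort, gamma = 1) {
  do.call(rbind, lapply(seq_len(cfg$n_subjects), function(i) {
    deg <- nodeDegree(generateConnectome(cfg, i))
    data.frame(subject_id = cohort$subject_id[i],
               node_id = seq_along(deg) - 1L, gamma = gamma,
               metric = "degree", value = deg,
               stringsAsFactors = FALSE)
  }))
}

# constant-baseline long table with an exact planted linear effect
exactLongTable <- function(beta, nSubjects = 12, nNodes = 5) {
  set.seed(99)
  trait <- rnorm(nSubjects)
  expand <- expand.grid(subject = seq_len(nSubjects),
                        node = seq_len(nNodes))
  data.frame(subject_id = sprintf("S%02d", expand$subject),
             node_id = expand$node - 1L,
             value = 10 + beta * trait[expand$subject],
             trait_c = trait[expand$subject],
             sex_c = rep(c(-0.5, 0.5), length.out = nSubjects)[expand$subject],
             age_c = 0,
             scan_group = rep(c("G1", "G2"),
                              length.out = nSubjects)[expand$subject],
             stringsAsFactors = FALSE)
}

# degree + betweenness metric table (the family used in FDR calibration)
twoMetricTable <- function(cfg, cohort, gamma = 1) {
  n <- cfg$n_nodes
  do.call(rbind, lapply(seq_len(cfg$n_subjects), function(i) {
    conn <- generateConnectome(cfg, i)
    data.frame(subject_id = cohort$subject_id[i],
               node_id = rep(seq_len(n) - 1L, 2), gamma = gamma,
               metric = rep(c("degree", "betweenness"), each = n),
               value = c(nodeDegree(conn), nodeBetweenness(conn)),
               stringsAsFactors = FALSE)
  }))
}
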