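test_that("modularity Q closed forms", {
  a <- randomGraph(10, 0.4, seed = 1)
  # one module at gamma = 1: Q = 1 - gamma = 0
  expect_equal(modularityQ(a, rep(1, 10), gamma = 1), 0, tolerance = 1e-12)
  # two disconnected K5s under the correct bipartition
  expect_equal(modularityQ(twoCliques(5), rep(1:2, each = 5), 1), 0.5)
  # singleton partition: Q = -gamma * sum(k_i^2) / (2m)^2
  k <- rowSums(a)
  m2 <- sum(a)
  for (g in c(0.5, 1, 2))
    expect_equal(modularityQ(a, 1:10, g), -g * sum(k^2) / m2^2)
  expect_error(modularityQ(matrix(0, 3, 3), c(1, 1, 2)), "no edges")
})

test_that("modularity agrees with the igraph oracle at several gammas", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    a <- randomGraph(12, 0.4, seed = 100 + s)
    if (sum(a) == 0) next
    m <- sample(1:4, 12, replace = TRUE)
    m <- as.integer(match(m, unique(m)))
    g <- igraph::graph_from_adjacency_matrix(a, "undirected")
    for (gam in c(0.3, 1, 2.5))
      expect_equal(modularityQ(a, m, gam),
                   igraph::modularity(g, m, resolution = gam),
                   tolerance = 1e-12)
  }
})

test_that("Louvain with fine-tuning solves canonical benchmarks", {
  p <- louvainFinetune(twoCliques(5), gamma = 1, seed = 1)
  expect_equal(modularityValue(p), 0.5)
  expect_equal(nModules(p), 2L)
  expect_equal(moduleAssignment(p), rep(1:2, each = 5))

  ring <- ringOfCliques(8, 5)
  pr <- louvainFinetune(ring, gamma = 1, seed = 2)
  expect_equal(nModules(pr), 8L)
  expect_equal(moduleAssignment(pr), rep(1:8, each = 5))
})

test_that("returned partitions are locally optimal and beat trivial ones", {
  for (s in 1:4) {
    a <- randomGraph(18, 0.3, seed = 200 + s)
    if (sum(a) == 0) next
    p <- louvainFinetune(a, gamma = 1, seed = s)
    q <- modularityValue(p)
    m <- moduleAssignment(p)
    expect_gte(q, modularityQ(a, rep(1, 18), 1))
    expect_gte(q, modularityQ(a, 1:18, 1))
    # no single-node move (to any existing or new module) increases Q
    labels <- c(unique(m), max(m) + 1L)
    for (v in 1:18) for (lab in labels) {
      if (lab == m[v]) next
      m2 <- m
      m2[v] <- lab
      expect_lte(modularityQ(a, as.integer(match(m2, unique(m2))), 1),
                 q + 1e-12)
    }
  }
})

test_that("Louvain is deterministic given the seed", {
  a <- randomGraph(25, 0.25, seed = 9)
  p1 <- louvainFinetune(a, gamma = 1.3, seed = 77)
  p2 <- louvainFinetune(a, gamma = 1.3, seed = 77)
  expect_identical(moduleAssignment(p1), moduleAssignment(p2))
  expect_identical(modularityValue(p1), modularityValue(p2))
})

test_that("higher resolution yields at least as many modules", {
  a <- randomGraph(30, 0.2, seed = 5)
  lo <- louvainFinetune(a, gamma = 0.3, seed = 11)
  hi <- louvainFinetune(a, gamma = 5, seed = 11)
  expect_gte(nModules(hi), nModules(lo))
})

test_that("the default gamma grid has 48 resolutions", {
  a <- twoCliques(5)
  sw <- gammaSweep(a, seed = 1)
  expect_length(sw, 48L)
  expect_equal(gammaValue(sw[[1]]), 0.3)
  expect_equal(gammaValue(sw[[48]]), 5.0)
  # single-gamma grid reduces to one fine-tuned run
  one <- gammaSweep(a, gammas = 1, seed = 4)
  direct <- louvainFinetune(a, gamma = 1, seed = spawnSeeds(4, 1))
  expect_identical(moduleAssignment(one[[1]]), moduleAssignment(direct))
})

test_that("agreement matrix counts co-assignments", {
  part <- ModularPartition(rep(1:2, each = 3))
  ag <- agreementMatrix(replicate(10, part, simplify = FALSE))
  cts <- agreementCounts(ag)
  expect_true(all(cts %in% c(0L, 10L)))
  expect_equal(diag(cts), rep(10L, 6))
  expect_equal(cts[1, 2], 10L)
  expect_equal(cts[1, 4], 0L)

  # two partitions, one pair together exactly once
  p1 <- c(1, 1, 2)
  p2 <- c(1, 2, 2)
  ag2 <- agreementCounts(agreementMatrix(list(p1, p2)))
  expect_equal(ag2[1, 2], 1L)
  expect_equal(ag2[2, 3], 1L)
  expect_equal(ag2[1, 3], 0L)

  expect_error(agreementMatrix(list(c(1, 2), c(1, 2, 3))), "node sets")
})

test_that("agreement entries match a direct pairwise tally", {
  set.seed(21)
  parts <- lapply(1:7, function(i) sample(1:3, 9, replace = TRUE))
  cts <- agreementCounts(agreementMatrix(parts))
  for (i in 1:8) for (j in (i + 1):9) {
    tally <- sum(vapply(parts, function(m) m[i] == m[j], logical(1)))
    expect_equal(cts[i, j], tally)
  }
})

test_that("consensus of identical partitions is idempotent", {
  part <- ModularPartition(rep(1:3, each = 4))
  ag <- agreementMatrix(replicate(8, part, simplify = FALSE))
  cons <- consensusPartition(ag, reps = 10, seed = 3)
  expect_equal(moduleAssignment(cons), moduleAssignment(part))
})

test_that("consensus of two conflicting partitions settles on one", {
  p1 <- c(1, 1, 2, 2)
  p2 <- c(1, 2, 1, 2)
  ag <- agreementMatrix(list(p1, p2))
  cons <- consensusPartition(ag, reps = 20, seed = 5)
  m <- moduleAssignment(cons)
  expect_true(identical(m, as.integer(p1)) || identical(m, as.integer(p2)))
  cons2 <- consensusPartition(ag, reps = 20, seed = 5)
  expect_identical(moduleAssignment(cons2), m)
})

test_that("consensus recovers the planted cohort structure", {
  skip_if_not_installed("mclust")
  cfg <- cohortConfig(n_subjects = 12, n_nodes = 48, n_modules_planted = 4,
                      p_in = 0.4, p_out = 0.05, seed = 31)
  parts <- lapply(1:12, function(i)
    louvainFinetune(connValues(generateConnectome(cfg, i)),
                    gamma = 1, seed = 500 + i))
  cons <- consensusPartition(agreementMatrix(parts), reps = 50, seed = 8)
  ari <- mclust::adjustedRandIndex(moduleAssignment(cons),
                                   plantedPartition(cfg))
  expect_gte(ari, 0.9)
})

test_that("module screen keeps reproducible modules and flags one-module", {
  part <- ModularPartition(rep(1:3, each = 5))
  parts <- replicate(10, part, simplify = FALSE)
  sig <- moduleSignificance(consensusPartition(agreementMatrix(parts),
                                               reps = 5, seed = 1),
                            parts, nNull = 50, seed = 2)
  expect_true(all(sig$keep))

  single <- ModularPartition(rep(1, 6))
  expect_warning(
    sig1 <- moduleSignificance(single, replicate(4, ModularPartition(
      c(1, 1, 1, 2, 2, 2)), simplify = FALSE), nNull = 20, seed = 3),
    "vacuously")
  expect_true(all(sig1$keep))
})

test_that("module screen is calibrated near 5% under random partitions", {
  set.seed(60)
  kept <- 0
  total <- 0
  for (rep in 1:25) {
    parts <- lapply(1:8, function(i)
      ModularPartition(sample(1:4, 20, replace = TRUE)))
    cons <- ModularPartition(sample(1:4, 20, replace = TRUE))
    sig <- moduleSignificance(cons, parts, nNull = 60, seed = 700 + rep)
    kept <- kept + sum(sig$keep & !is.na(sig$observed))
    total <- total + sum(!is.na(sig$observed))
  }
  expect_lt(kept / total, 0.15)
})

test_that("modularity-trait correlation behaves under null and signal", {
  set.seed(71)
  subj <- sprintf("S%03d", 1:100)
  gs <- seq(0.5, 1.5, by = 0.5)
  qt <- expand.grid(subject_id = subj, gamma = gs,
                    stringsAsFactors = FALSE)
  qshift <- rnorm(100)
  qt$Q <- 0.5 + 0.05 * qshift[match(qt$subject_id, subj)] +
    rnorm(nrow(qt), 0, 0.01)

  nullAbs <- vapply(1:10, function(i) {
    nullTrait <- setNames(rnorm(100), subj)
    abs(modularityTraitCorrelation(qt, nullTrait)$mean_r)
  }, numeric(1))
  expect_lt(mean(nullAbs), 0.1)
  nullTrait <- setNames(rnorm(100), subj)

  perfTrait <- setNames(qshift + rnorm(100, 0, 1e-4), subj)
  resPerf <- modularityTraitCorrelation(qt, perfTrait)
  expect_true(all(resPerf$per_gamma$r > 0.9))

  # planted correlation ~0.3 between trait and the subject Q shift
  # (population r = 0.3 * 0.05 / sqrt(0.05^2 + 0.01^2) = 0.294)
  planted <- setNames(0.3 * qshift + sqrt(1 - 0.09) * rnorm(100), subj)
  resP <- modularityTraitCorrelation(qt, planted)
  expect_lt(abs(resP$mean_r - 0.3), 0.1)

  qt0 <- qt
  qt0$Q[qt0$gamma == 0.5] <- 0.4
  expect_warning(res0 <- modularityTraitCorrelation(qt0, nullTrait),
                 "zero variance")
  expect_equal(nrow(res0$per_gamma), 2L)
})

test_that("partition files round-trip with gamma and Q", {
  p <- louvainFinetune(twoCliques(5), gamma = 1.7, seed = 2)
  path <- tempfile(fileext = ".csv")
  writePartition(p, path)
  back <- readPartition(path)
  expect_equal(moduleAssignment(back), moduleAssignment(p))
  expect_equal(gammaValue(back), 1.7)
  expect_equal(modularityValue(back), modularityValue(p), tolerance = 1e-9)
})
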