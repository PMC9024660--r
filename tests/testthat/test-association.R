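test_that("long tables have one row per subject-node pair", {
  cfg <- cohortConfig(n_subjects = 20, n_nodes = 15, n_modules_planted = 3,
                      seed = 6)
  coh <- generateCohort(cfg)
  mt <- degreeMetricTable(cfg, coh)
  lt <- buildLongTable(mt, coh, 1, 0:4, "degree", "ve_t")
  expect_equal(nrow(lt), 100L)
  expect_setequal(names(lt), c("subject_id", "node_id", "value", "trait_c",
                               "sex_c", "age_c", "scan_group"))
  expect_setequal(unique(lt$sex_c), c(-0.5, 0.5))
  expect_equal(mean(lt$age_c[!duplicated(lt$subject_id)]), 0,
               tolerance = 1e-10)
  expect_error(buildLongTable(mt, coh, 1, integer(0)), "empty module")

  cohNA <- coh
  cohNA$ve_t[3] <- NA
  expect_message(ltNA <- buildLongTable(mt, cohNA, 1, 0:4), "1 subject")
  expect_equal(nrow(ltNA), 95L)
  expect_equal(attr(ltNA, "n_excluded"), 1L)
})

test_that("a noiseless planted slope is recovered exactly", {
  lt <- exactLongTable(beta = 3.2)
  res <- suppressWarnings(fitModuleModel(lt))
  expect_lt(abs(res$beta_trait$estimate - 3.2), 1e-6)
})

test_that("partial sex slopes obey the contrast algebra", {
  cfg <- cohortConfig(n_subjects = 24, n_nodes = 20, n_modules_planted = 2,
                      planted_beta = 3, planted_beta_sex = -2, seed = 9)
  coh <- generateCohort(cfg)
  mt <- plantEffect(degreeMetricTable(cfg, coh), coh, cfg)
  res <- fitModuleModel(buildLongTable(mt, coh, 1,
                                       which(plantedPartition(cfg) == 1) - 1L))
  b <- res$beta_trait$estimate
  bi <- res$beta_sex_int$estimate
  expect_equal(unname(res$partial_beta_by_sex["female"]), b - 0.5 * bi)
  expect_equal(unname(res$partial_beta_by_sex["male"]), b + 0.5 * bi)
})

test_that("group term is dropped with a warning when only one group", {
  lt <- exactLongTable(beta = 1)
  lt$scan_group <- "G1"
  lt$value <- lt$value + rnorm(nrow(lt), 0, 0.5)
  expect_warning(res <- fitModuleModel(lt), "group term dropped")
  expect_false(any(grepl("scan_group", deparse(formula(res$fit)))))
})

test_that("modules with a single node are rejected", {
  lt <- exactLongTable(beta = 1)
  expect_error(fitModuleModel(lt[lt$node_id == 0, ]), "at least 2 nodes")
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(fdrCorrect(0.03), 0.03)
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdrCorrect(rep(0.2, 5)), rep(0.2, 5))
  set.seed(31)
  p <- runif(40)
  q <- fdrCorrect(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(fdrCorrect(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("residual screen: alpha 0 disables exclusions; heavy tails are caught", {
  cfg <- cohortConfig(n_subjects = 25, n_nodes = 16, n_modules_planted = 2,
                      planted_beta = 2, seed = 15)
  coh <- generateCohort(cfg)
  mt <- plantEffect(degreeMetricTable(cfg, coh), coh, cfg)
  nodes <- which(plantedPartition(cfg) == 1) - 1L
  lt <- buildLongTable(mt, coh, 1, nodes)
  scr0 <- residualScreen(lt, alpha_ad = 0)
  expect_length(scr0$excluded, 0L)
  expect_equal(scr0$screened$beta_trait$estimate,
               scr0$initial$beta_trait$estimate)

  # inject grossly heavy-tailed residuals into one node
  hits <- vapply(1:10, function(s) {
    set.seed(800 + s)
    lt2 <- lt
    bad <- lt2$node_id == nodes[1]
    lt2$value[bad] <- lt2$value[bad] + 40 * rt(sum(bad), df = 1)
    scr <- residualScreen(lt2, alpha_ad = 0.05)
    nodes[1] %in% scr$excluded
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("screen exclusion rate under Gaussian residuals is near nominal", {
  rates <- vapply(1:8, function(s) {
    lt <- exactLongTable(beta = 1, nSubjects = 20, nNodes = 10)
    set.seed(900 + s)
    lt$value <- lt$value + rnorm(nrow(lt))
    scr <- suppressWarnings(residualScreen(lt, alpha_ad = 0.05))
    length(scr$excluded) / 10
  }, numeric(1))
  expect_lt(mean(rates), 0.15)
})

test_that("cross-gamma model is consistent with per-gamma fits", {
  cfg <- cohortConfig(n_subjects = 25, n_nodes = 16, n_modules_planted = 2,
                      planted_beta = 3, seed = 19)
  coh <- generateCohort(cfg)
  mt <- plantEffect(degreeMetricTable(cfg, coh), coh, cfg)
  nodes <- which(plantedPartition(cfg) == 1) - 1L
  lt <- buildLongTable(mt, coh, 1, nodes)
  single <- fitModuleModel(lt)

  # duplicated tables: same fixed effect up to degrees of freedom
  dup <- crossGammaModel(list("1" = lt, "2" = lt))
  expect_equal(dup$beta_trait$estimate, single$beta_trait$estimate,
               tolerance = 1e-4)

  # single table falls back with a warning
  expect_warning(fb <- crossGammaModel(list("1" = lt)), "single gamma")
  expect_equal(fb$beta_trait$estimate, single$beta_trait$estimate)
})

test_that("cross-gamma estimate tracks the mean of per-gamma effects", {
  cfg <- cohortConfig(n_subjects = 30, n_nodes = 16, n_modules_planted = 2,
                      planted_beta = 3, seed = 21)
  coh <- generateCohort(cfg)
  nodes <- which(plantedPartition(cfg) == 1) - 1L
  mtA <- plantEffect(degreeMetricTable(cfg, coh, gamma = 1), coh, cfg)
  mtB <- plantEffect(degreeMetricTable(cfg, coh, gamma = 2), coh, cfg)
  ltA <- buildLongTable(mtA, coh, 1, nodes)
  ltB <- buildLongTable(mtB, coh, 2, nodes)
  bA <- fitModuleModel(ltA)$beta_trait$estimate
  bB <- fitModuleModel(ltB)$beta_trait$estimate
  cross <- crossGammaModel(list("1" = ltA, "2" = ltB))$beta_trait$estimate
  expect_equal(cross, mean(c(bA, bB)), tolerance = 0.1 * abs(mean(c(bA, bB))))

  # an effect present at one gamma only is attenuated in the stacked model
  mtNull <- degreeMetricTable(cfg, coh, gamma = 2)
  cfg0 <- cfg
  cfg0$planted_beta <- 0
  mtNull <- plantEffect(mtNull, coh, cfg0)
  ltNull <- buildLongTable(mtNull, coh, 2, nodes)
  att <- crossGammaModel(list("1" = ltA, "2" = ltNull))$beta_trait$estimate
  expect_lt(att, bA)
})

test_that("BLUPs are centred and track the planted node slopes", {
  cfg <- cohortConfig(n_subjects = 80, n_nodes = 40, n_modules_planted = 4,
                      planted_beta = 3.2, seed = 33)
  coh <- generateCohort(cfg)
  mt <- plantEffect(degreeMetricTable(cfg, coh), coh, cfg)
  nodes <- which(plantedPartition(cfg) == 1) - 1L
  res <- fitModuleModel(buildLongTable(mt, coh, 1, nodes))
  expect_equal(mean(res$blups), 0, tolerance = 0.2)
  slopes <- attr(mt, "planted")$node_slope
  expect_gte(cor(res$blups[names(slopes)], slopes), 0.5)
})

test_that("ICE curves are linear with the fitted slopes", {
  cfg <- cohortConfig(n_subjects = 20, n_nodes = 12, n_modules_planted = 2,
                      planted_beta = 3, planted_beta_sex = -1, seed = 27)
  coh <- generateCohort(cfg)
  mt <- plantEffect(degreeMetricTable(cfg, coh), coh, cfg)
  res <- fitModuleModel(buildLongTable(mt, coh, 1,
                                       which(plantedPartition(cfg) == 1) - 1L))
  grid <- seq(-2, 2, length.out = 5)
  ice <- iceCurves(res, grid)
  expect_equal(nrow(ice), 20 * 5)
  slopes <- vapply(split(ice, ice$subject_id), function(d)
    unname(coef(lm(predicted ~ trait, d))[2]), numeric(1))
  b <- res$beta_trait$estimate
  bi <- res$beta_sex_int$estimate
  sexc <- setNames(ifelse(coh$sex == "female", -0.5, 0.5), coh$subject_id)
  expect_equal(slopes, b + sexc[names(slopes)] * bi, tolerance = 1e-8,
               ignore_attr = TRUE)
  # sex-balanced cohorts: mean curve slope matches the fixed effect
  expect_equal(mean(slopes), b + mean(sexc) * bi, tolerance = 1e-8)
})

test_that("dropping a homogeneous group effect barely moves the estimate", {
  cfg <- cohortConfig(n_subjects = 30, n_nodes = 16, n_modules_planted = 2,
                      planted_beta = 3, group_sd = 0, seed = 41)
  coh <- generateCohort(cfg)
  mt <- plantEffect(degreeMetricTable(cfg, coh), coh, cfg)
  lt <- buildLongTable(mt, coh, 1, which(plantedPartition(cfg) == 1) - 1L)
  withGrp <- fitModuleModel(lt)
  lt1 <- lt
  lt1$scan_group <- "G1"
  noGrp <- suppressWarnings(fitModuleModel(lt1))
  expect_lt(abs(withGrp$beta_trait$estimate - noGrp$beta_trait$estimate),
            withGrp$beta_trait$se)
})

test_that("associationScan assembles a tidy FDR-adjusted table", {
  cfg <- cohortConfig(n_subjects = 20, n_nodes = 20, n_modules_planted = 4,
                      planted_beta = 4, seed = 55)
  coh <- generateCohort(cfg)
  mt <- do.call(rbind, lapply(1:20, function(i)
    nodalMetrics(generateConnectome(cfg, i), plantedPartition(cfg),
                 subject_id = coh$subject_id[i], gamma = 1)))
  mt <- plantEffect(mt, coh, cfg)
  mods <- split(0:19, plantedPartition(cfg))
  scan <- associationScan(mt, coh, list("1" = mods),
                          metrics = c("degree", "participation"),
                          traits = "ve_t")
  expect_equal(nrow(scan$table), 4 * 2)
  expect_true(all(scan$table$q >= scan$table$p))
  expect_true(all(scan$table$ci_low <= scan$table$estimate &
                    scan$table$estimate <= scan$table$ci_high))
  # the planted (module 1, degree) effect is the top-ranked discovery
  best <- scan$table[which.min(scan$table$q), ]
  expect_equal(best$module, 1)
  expect_equal(best$metric, "degree")
})
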