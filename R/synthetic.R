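#' Configuration of a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort composition,
#' planted modular connectome structure, questionnaire generation targets,
#' and the variance components of the planted trait -> topology effect.
#' Defaults emulate the study conditions the pipeline is designed for:
#' 116 subjects (62 female) in 4 scanning groups (38/28/22/28), ages ~
#' N(23, 3) truncated to [18, 35], subscale consistencies 0.92/0.95, a
#' subscale correlation of 0.315, a standardized female - male difference of
#' 0.90 on vicarious experience, a 418-node connectome, and a planted trait
#' slope of 3.2 on degree (per SD of the transformed trait).
#'
#' @param n_subjects,n_nodes,n_modules_planted cohort and graph dimensions.
#' @param p_in,p_out within/between-module edge probabilities (mode A);
#'   detectable planted structure requires `p_in > p_out`.
#' @param trait_corr target Pearson correlation between the two raw subscale
#'   scores.
#' @param sex_effect_d standardized female - male difference on the VE score.
#' @param female_fraction fraction of female subjects.
#' @param alpha_ve,alpha_iu target Cronbach's alpha per subscale (in (0, 1)).
#' @param planted_beta trait slope planted on the target metric in the target
#'   module (units: metric per SD of transformed trait).
#' @param planted_beta_sex trait-by-sex interaction slope (sex coded
#'   female = -0.5, male = +0.5).
#' @param target_module planted module index carrying the effect.
#' @param target_metric metric the effect is planted on.
#' @param subject_sd,node_slope_sd,group_sd,residual_sd variance components
#'   (SDs) of the planted-effect model.
#' @param n_groups number of scanning groups.
#' @param group_props group membership probabilities (recycled/normalised).
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param seed master seed; every stochastic stage derives child seeds from
#'   it.
#' @return a classed list (`CohortConfig`).
#' @export
cohortConfig <- function(n_subjects = 116L, n_nodes = 418L,
                         n_modules_planted = 6L,
                         p_in = 0.4, p_out = 0.05,
                         trait_corr = 0.315, sex_effect_d = 0.90,
                         female_fraction = 62 / 116,
                         alpha_ve = 0.92, alpha_iu = 0.95,
                         planted_beta = 3.2, planted_beta_sex = 0,
                         target_module = 1L, target_metric = "degree",
                         subject_sd = 3, node_slope_sd = 2,
                         group_sd = 1, residual_sd = 5,
                         n_groups = 4L,
                         group_props = c(38, 28, 22, 28) / 116,
                         age_mean = 23, age_sd = 3,
                         age_range = c(18, 35), seed = 1L) {
  cfg <- mget(names(formals()))
  if (cfg$n_subjects < 1 || cfg$n_nodes < 1 || cfg$n_modules_planted < 1)
    stop("n_subjects, n_nodes and n_modules_planted must be >= 1",
         call. = FALSE)
  sds <- c(subject_sd, node_slope_sd, group_sd, residual_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (p_in <= 0 || p_in > 1 || p_out < 0 || p_out >= 1)
    stop("p_in must be in (0,1], p_out in [0,1)", call. = FALSE)
  if (p_in <= p_out)
    warning("p_in <= p_out: planted modules will not be detectable")
  for (a in c(alpha_ve, alpha_iu))
    if (a <= 0 || a >= 1)
      stop("alpha targets must lie strictly in (0, 1); got ", a,
           call. = FALSE)
  if (abs(trait_corr) >= 1)
    stop("trait_corr must lie in (-1, 1)", call. = FALSE)
  if (female_fraction < 0 || female_fraction > 1)
    stop("female_fraction must lie in [0, 1]", call. = FALSE)
  if (target_module > n_modules_planted)
    stop("target_module exceeds n_modules_planted", call. = FALSE)
  cfg$group_props <- rep_len(cfg$group_props, n_groups)
  cfg$group_props <- cfg$group_props / sum(cfg$group_props)
  structure(cfg, class = "CohortConfig")
}

# ---- item-model calibration -------------------------------------------------
# Responses are thresholded latent normals: 5 categories from equal-width
# cuts at (-1.5, -0.5, 0.5, 1.5) on the latent item scale. Discretization
# attenuates correlations, so the latent loadings, sex shift and factor
# correlation are solved (by 1-D numerical integration of the discretized
# bivariate-normal moments) so that the OBSERVED alpha, Cohen's d and
# subscale correlation match the configured targets.

.cuts <- c(-1.5, -0.5, 0.5, 1.5)

# P(X > a, Y > b), (X, Y) standard bivariate normal with correlation rho,
# means mux, muy
.biTail <- function(a, b, rho, mux = 0, muy = 0) {
  a <- a - mux; b <- b - muy
  if (abs(rho) < 1e-12)
    return(stats::pnorm(a, lower.tail = FALSE) *
             stats::pnorm(b, lower.tail = FALSE))
  f <- function(u) stats::dnorm(u) *
    stats::pnorm((b - rho * u) / sqrt(1 - rho^2), lower.tail = FALSE)
  stats::integrate(f, lower = a, upper = Inf, rel.tol = 1e-9)$value
}

# moments of the category score c(X) = #cuts exceeded, X ~ N(mu, 1)
.catMean <- function(mu) sum(stats::pnorm(.cuts - mu, lower.tail = FALSE))
.catVar <- function(mu) {
  p <- stats::pnorm(.cuts - mu, lower.tail = FALSE)
  ecc <- 0
  for (j in seq_along(.cuts)) for (k in seq_along(.cuts))
    ecc <- ecc + p[max(j, k)]
  ecc - sum(p)^2
}
# E[c(X) c(Y)] for items with latent correlation rho and means mux, muy
.catCross <- function(rho, mux = 0, muy = 0) {
  s <- 0
  for (a in .cuts) for (b in .cuts) s <- s + .biTail(a, b, rho, mux, muy)
  s
}

# pooled-over-sex observed moments for a subscale with loading lam and
# latent sex shift del (female - male, on the standardized factor)
.subscaleMoments <- function(lam, del, p, k = 15) {
  muF <- lam * del * (1 - p)
  muM <- -lam * del * p
  eF <- .catMean(muF); eM <- .catMean(muM)
  e <- p * eF + (1 - p) * eM
  vF <- .catVar(muF); vM <- .catVar(muM)
  vbar <- p * (vF + (eF - e)^2) + (1 - p) * (vM + (eM - e)^2)
  covF <- .catCross(lam^2, muF, muF) - eF^2
  covM <- .catCross(lam^2, muM, muM) - eM^2
  cbar <- p * (covF + (eF - e)^2) + (1 - p) * (covM + (eM - e)^2)
  varSum <- k * vbar + k * (k - 1) * cbar
  varSumF <- k * vF + k * (k - 1) * covF
  varSumM <- k * vM + k * (k - 1) * covM
  alpha <- k / (k - 1) * (1 - k * vbar / varSum)
  dObs <- k * (eF - eM) / sqrt(p * varSumF + (1 - p) * varSumM)
  list(alpha = alpha, d = dObs, e = e, varSum = varSum,
       eF = eF, eM = eM)
}

.alphaToLambda <- function(alphaTarget, del, p) {
  stats::uniroot(function(l) .subscaleMoments(l, del, p)$alpha - alphaTarget,
                 c(0.05, 0.999), tol = 1e-6)$root
}

.calibrateItemModel <- function(cfg) {
  key <- paste(cfg$alpha_ve, cfg$alpha_iu, cfg$sex_effect_d,
               cfg$trait_corr, cfg$female_fraction, sep = "|")
  if (!is.null(.calibCache[[key]])) return(.calibCache[[key]])
  p <- cfg$female_fraction
  lam2 <- .alphaToLambda(cfg$alpha_iu, 0, p)
  # jointly solve loading and sex shift for the VE subscale
  lam1 <- .alphaToLambda(cfg$alpha_ve, 0, p)
  del <- 0
  if (cfg$sex_effect_d != 0 && p > 0 && p < 1) {
    for (it in 1:4) {
      del <- stats::uniroot(
        function(d) .subscaleMoments(lam1, d, p)$d - cfg$sex_effect_d,
        c(-6, 6), tol = 1e-6)$root
      lam1 <- .alphaToLambda(cfg$alpha_ve, del, p)
    }
  }
  # factor correlation producing the target observed sum-score correlation
  m1 <- .subscaleMoments(lam1, del, p)
  m2 <- .subscaleMoments(lam2, 0, p)
  k <- 15
  rhoG <- 0
  if (cfg$trait_corr != 0) {
    muF <- lam1 * del * (1 - p); muM <- -lam1 * del * p
    crossCov <- function(rg) {
      r <- lam1 * lam2 * rg
      cF <- .catCross(r, muF, 0) - .catMean(muF) * .catMean(0)
      cM <- .catCross(r, muM, 0) - .catMean(muM) * .catMean(0)
      p * cF + (1 - p) * cM
    }
    target <- cfg$trait_corr * sqrt(m1$varSum * m2$varSum) / k^2
    rhoG <- stats::uniroot(function(rg) crossCov(rg) - target,
                           c(-0.999, 0.999), tol = 1e-6)$root
  }
  out <- list(lambda1 = lam1, lambda2 = lam2, delta = del, rho_g = rhoG)
  .calibCache[[key]] <- out
  out
}

.calibCache <- new.env(parent = emptyenv())

# ---- cohort -----------------------------------------------------------------

#' Generate a synthetic cohort of subjects
#'
#' Draws demographics (sex, age, scanning group), two correlated latent
#' empathy factors, and 30 ordinal item responses from a two-factor model
#' (odd items load on the first factor, even items on the second; responses
#' are thresholded latent normals with 5 equal-width categories). The latent
#' loadings, sex shift and factor correlation are calibrated so that the
#' observed subscale alphas, the female - male standardized difference on VE,
#' and the VE-IU correlation converge to the configured targets as the cohort
#' grows. Scores are computed with [scoreCohort()] (Box-Cox transformed and
#' standardized). Deterministic given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return data.frame, one row per subject: `subject_id, sex, age,
#'   scan_group, item_01..item_30, ve_raw, iu_raw, ve_t, iu_t`; the config is
#'   attached as attribute `"config"`.
#' @export
#' @examples
#' coh <- generateCohort(cohortConfig(n_subjects = 40, seed = 7))
#' cor(coh$ve_raw, coh$iu_raw)
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  cal <- .calibrateItemModel(config)
  n <- config$n_subjects
  p <- config$female_fraction
  seeds <- spawnSeeds(config$seed, 3L)
  cohort <- withSeed(seeds[1], {
    nF <- round(p * n)
    sex <- rep("male", n)
    sex[sample.int(n, nF)] <- "female"
    age <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        a <- stats::rnorm(1, config$age_mean, config$age_sd)
        if (a >= config$age_range[1] && a <= config$age_range[2]) break
      }
      age[i] <- round(a)
    }
    grp <- sample(sprintf("G%d", seq_len(config$n_groups)), n,
                  replace = TRUE, prob = config$group_props)
    # latent factors (unit within-sex variance), sex shift on factor 1
    z <- matrix(stats::rnorm(2 * n), n, 2)
    g1 <- z[, 1]
    g2 <- cal$rho_g * z[, 1] + sqrt(1 - cal$rho_g^2) * z[, 2]
    f1 <- g1 + cal$delta * ((sex == "female") - p)
    f2 <- g2
    items <- matrix(0L, n, 30)
    for (j in 1:30) {
      lam <- if (j %% 2 == 1) cal$lambda1 else cal$lambda2
      f <- if (j %% 2 == 1) f1 else f2
      x <- lam * f + sqrt(1 - lam^2) * stats::rnorm(n)
      items[, j] <- 1L + rowSums(outer(x, .cuts, ">"))
    }
    colnames(items) <- sprintf("item_%02d", 1:30)
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               sex = sex, age = age, scan_group = grp, items,
               stringsAsFactors = FALSE)
  })
  cohort <- scoreCohort(cohort)
  attr(cohort, "config") <- config
  cohort
}

#' Planted module membership of the synthetic connectome
#'
#' Nodes are split into `n_modules_planted` equal blocks (floor division;
#' the remainder joins the last block).
#'
#' @param config a [cohortConfig()].
#' @return integer membership vector of length `n_nodes`.
#' @export
plantedPartition <- function(config) {
  n <- config$n_nodes
  k <- config$n_modules_planted
  size <- n %/% k
  m <- rep(seq_len(k), each = size)
  c(m, rep(k, n - length(m)))
}

# per-subject child seeds for connectome generation
.subjectSeeds <- function(config) {
  seeds <- spawnSeeds(config$seed, 3L)
  spawnSeeds(seeds[2], config$n_subjects)
}

#' Generate one subject's synthetic connectome
#'
#' Mode `"adjacency"` draws a binary planted-partition graph directly:
#' within-module edges with probability `p_in`, between-module edges with
#' `p_out`. Mode `"timeseries"` draws nodal time series from a
#' block-structured correlation matrix (`rho_in` within modules, `rho_out`
#' between) and pushes them through the real connectome chain
#' ([fisherZConnectome()] then [proportionalThreshold()]), exercising the
#' full pipeline. Both modes are reproducible given the configuration seed
#' and the subject index.
#'
#' @param config a [cohortConfig()].
#' @param subject subject index (1-based), used to derive the child seed.
#' @param mode `"adjacency"` (fast test path) or `"timeseries"`
#'   (integration path).
#' @param nTimepoints,rho_in,rho_out,density time-series mode parameters.
#' @return binary [Connectome-class] with the planted membership attached as
#'   attribute `"membership"`.
#' @export
generateConnectome <- function(config, subject = 1L,
                               mode = c("adjacency", "timeseries"),
                               nTimepoints = 200L, rho_in = 0.8,
                               rho_out = 0, density = 0.10) {
  mode <- match.arg(mode)
  m <- plantedPartition(config)
  n <- config$n_nodes
  seed <- .subjectSeeds(config)[subject]
  conn <- if (mode == "adjacency") {
    withSeed(seed, {
      same <- outer(m, m, "==")
      pm <- ifelse(same, config$p_in, config$p_out)
      adj <- matrix(0, n, n)
      ut <- upper.tri(adj)
      adj[ut] <- as.numeric(stats::runif(sum(ut)) < pm[ut])
      Connectome(adj + t(adj), kind = "binary")
    })
  } else {
    ts <- generateTimeSeries(config, subject, nTimepoints, rho_in, rho_out)
    proportionalThreshold(fisherZConnectome(ts), density = density)
  }
  attr(conn, "membership") <- m
  conn
}

#' Generate block-structured nodal time series for one subject
#'
#' Time series are drawn from a multivariate normal whose correlation is
#' `rho_in` within planted modules and `rho_out` between them.
#'
#' @inheritParams generateConnectome
#' @return numeric matrix, `n_nodes` x `nTimepoints`.
#' @export
generateTimeSeries <- function(config, subject = 1L, nTimepoints = 200L,
                               rho_in = 0.8, rho_out = 0) {
  m <- plantedPartition(config)
  n <- config$n_nodes
  seed <- .subjectSeeds(config)[subject]
  C <- ifelse(outer(m, m, "=="), rho_in, rho_out)
  diag(C) <- 1
  L <- chol(C)
  withSeed(seed, t(L) %*% matrix(stats::rnorm(n * nTimepoints),
                                 n, nTimepoints))
}

#' Plant a trait -> topology effect into a nodal metric table
#'
#' Constructs the generative counterpart of the association model: for every
#' row of the target metric, the value becomes
#' `baseline + subject intercept + group intercept + residual`, and rows
#' whose node belongs to the target module additionally receive
#' `(planted_beta + node slope + planted_beta_sex * sex code) * trait`,
#' with node slopes ~ N(0, node_slope_sd), subject intercepts ~
#' N(0, subject_sd), group intercepts ~ N(0, group_sd), residuals ~
#' N(0, residual_sd), sex coded female = -0.5 / male = +0.5, and the trait
#' being the standardized Box-Cox VE score. Other metrics are untouched.
#'
#' @param metricTable tidy metric table
#'   (`subject_id, node_id, gamma, metric, value`).
#' @param cohort scored cohort table ([generateCohort()]).
#' @param config the [cohortConfig()] that produced them.
#' @param membership node module labels (defaults to the planted partition).
#' @param trait cohort column used as the planted predictor.
#' @return the metric table with planted values; the drawn effect components
#'   are attached as attribute `"planted"` (node slopes, subject and group
#'   intercepts).
#' @export
plantEffect <- function(metricTable, cohort, config,
                        membership = plantedPartition(config),
                        trait = "ve_t") {
  seed <- spawnSeeds(config$seed, 3L)[3]
  nodesAll <- sort(unique(metricTable$node_id))
  targetNodes <- nodesAll[membership[nodesAll + 1L] == config$target_module]
  if (!length(targetNodes))
    stop("target module has no nodes in the metric table", call. = FALSE)
  subjects <- unique(cohort$subject_id)
  groups <- unique(cohort$scan_group)
  drawn <- withSeed(seed, list(
    node_slope = stats::setNames(
      stats::rnorm(length(targetNodes), 0, config$node_slope_sd),
      targetNodes),
    subject_int = stats::setNames(
      stats::rnorm(length(subjects), 0, config$subject_sd), subjects),
    group_int = stats::setNames(
      stats::rnorm(length(groups), 0, config$group_sd), groups),
    resid_seed = spawnSeeds(seed, 1L)))
  rows <- metricTable$metric == config$target_metric
  tab <- metricTable
  sub <- tab[rows, ]
  tr <- stats::setNames(cohort[[trait]], cohort$subject_id)
  sx <- stats::setNames(ifelse(cohort$sex == "female", -0.5, 0.5),
                        cohort$subject_id)
  grpOf <- stats::setNames(cohort$scan_group, cohort$subject_id)
  sid <- as.character(sub$subject_id)
  inTarget <- sub$node_id %in% targetNodes
  slope <- numeric(nrow(sub))
  slope[inTarget] <- config$planted_beta +
    drawn$node_slope[as.character(sub$node_id[inTarget])] +
    config$planted_beta_sex * sx[sid[inTarget]]
  traitTerm <- ifelse(inTarget, slope * tr[sid], 0)
  resid <- withSeed(drawn$resid_seed,
                    stats::rnorm(nrow(sub), 0, config$residual_sd))
  sub$value <- sub$value + traitTerm + drawn$subject_int[sid] +
    drawn$group_int[grpOf[sid]] + resid
  tab[rows, ] <- sub
  attr(tab, "planted") <- drawn[c("node_slope", "subject_int", "group_int")]
  tab
}

#' Write a cohort configuration as YAML
#'
#' @param config a [cohortConfig()].
#' @param path output path.
#' @export
writeCohortConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeCohortConfig
#' @export
readCohortConfig <- function(path) {
  do.call(cohortConfig, yaml::read_yaml(path))
}
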