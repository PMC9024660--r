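#' @importFrom lme4 ranef fixef isSingular
#' @importFrom lmerTest lmer
NULL

#' Assemble the long modelling table for one (gamma, module, metric, trait)
#'
#' One row per (subject, node-in-module): the nodal metric value as outcome,
#' the standardized Box-Cox trait score, centered age, sex coded
#' female = -0.5 / male = +0.5, and the scanning group. Subjects with a
#' missing trait score are excluded (count reported via a message and the
#' `n_excluded` attribute).
#'
#' @param metricTable tidy metric table
#'   (`subject_id, node_id, gamma, metric, value`).
#' @param cohort scored cohort table.
#' @param gamma resolution to select.
#' @param moduleNodes integer vector of node ids forming the module.
#' @param metric metric name to select.
#' @param trait cohort column with the (transformed) trait score.
#' @return data.frame `subject_id, node_id, value, trait_c, sex_c, age_c,
#'   scan_group`.
#' @export
buildLongTable <- function(metricTable, cohort, gamma, moduleNodes,
                           metric = "degree", trait = "ve_t") {
  if (!length(moduleNodes)) stop("empty module", call. = FALSE)
  sel <- metricTable$metric == metric &
    abs(metricTable$gamma - gamma) < 1e-9 &
    metricTable$node_id %in% moduleNodes
  sub <- metricTable[sel, c("subject_id", "node_id", "value")]
  if (!nrow(sub))
    stop("no metric rows for metric '", metric, "' at gamma ", gamma,
         " in the given module", call. = FALSE)
  coh <- cohort[, c("subject_id", "sex", "age", "scan_group", trait)]
  ok <- !is.na(coh[[trait]])
  nExcl <- sum(!ok)
  if (nExcl) message(nExcl, " subject(s) excluded for missing trait score")
  coh <- coh[ok, ]
  out <- merge(sub, coh, by = "subject_id")
  out$trait_c <- out[[trait]]
  out$sex_c <- ifelse(out$sex == "female", -0.5, 0.5)
  out$age_c <- out$age - mean(coh$age)
  out <- out[order(out$subject_id, out$node_id),
             c("subject_id", "node_id", "value", "trait_c", "sex_c",
               "age_c", "scan_group")]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- nExcl
  out
}

# extract the tidy term table from a lmerTest fit
.termTable <- function(fit, conf = 0.95) {
  cf <- as.data.frame(stats::coef(summary(fit)))
  names(cf) <- c("estimate", "se", "df", "t", "p")
  tcrit <- stats::qt(1 - (1 - conf) / 2, cf$df)
  cf$ci_low <- cf$estimate - tcrit * cf$se
  cf$ci_high <- cf$estimate + tcrit * cf$se
  cf$term <- rownames(cf)
  rownames(cf) <- NULL
  cf[, c("term", "estimate", "se", "df", "t", "p", "ci_low", "ci_high")]
}

.mkResult <- function(fit, data, singularNote, nNodes, nExcluded = 0L) {
  terms <- .termTable(fit)
  bt <- terms[terms$term == "trait_c", ]
  bi <- terms[terms$term == "trait_c:sex_c", ]
  partial <- c(female = bt$estimate - 0.5 * bi$estimate,
               male = bt$estimate + 0.5 * bi$estimate)
  re <- lme4::ranef(fit)
  nodeGrp <- intersect(c("node_id", "gnode"), names(re))[1]
  blups <- if (!is.na(nodeGrp)) stats::setNames(re[[nodeGrp]][, "trait_c"],
                                                rownames(re[[nodeGrp]]))
  else numeric(0)
  structure(list(terms = terms, beta_trait = bt, beta_sex_int = bi,
                 partial_beta_by_sex = partial, blups = blups,
                 n_nodes_used = nNodes, n_excluded = nExcluded,
                 singular = lme4::isSingular(fit),
                 singular_note = singularNote, fit = fit, data = data),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat("Mixed-effects brain-behavior association (", x$n_nodes_used,
      " nodes", if (x$n_excluded) paste0(", ", x$n_excluded, " excluded"),
      ")\n", sep = "")
  print(x$terms, digits = 3, row.names = FALSE)
  cat(sprintf("partial trait slopes: female %.4g, male %.4g\n",
              x$partial_beta_by_sex["female"],
              x$partial_beta_by_sex["male"]))
  if (!is.null(x$singular_note)) cat("note:", x$singular_note, "\n")
  invisible(x)
}

# fit with a given RHS; on singularity drop the gamma-level random intercept
# first, then the scanning-group intercept; the node random slope is never
# dropped
.fitWithFallback <- function(data, randomTerms) {
  fixedPart <- "value ~ trait_c * sex_c + age_c"
  note <- NULL
  repeat {
    fml <- stats::as.formula(paste(c(fixedPart, randomTerms),
                                   collapse = " + "))
    fit <- suppressMessages(lmerTest::lmer(fml, data = data, REML = TRUE))
    if (!lme4::isSingular(fit)) return(list(fit = fit, note = note))
    droppable <- intersect(c("(1 | gamma_f)", "(1 | scan_group)"),
                           randomTerms)
    if (!length(droppable)) return(list(fit = fit, note = note))
    randomTerms <- setdiff(randomTerms, droppable[1])
    note <- paste(c(note, paste("singular fit: dropped", droppable[1])),
                  collapse = "; ")
  }
}

#' Fit the module-level mixed-effects association model
#'
#' REML fit of nodal topology on the trait score within one module at one
#' resolution: fixed effects `trait * sex + age`, random intercepts per
#' subject, a random trait slope per node (the individual-node deviations
#' from the module-level estimate, returned as BLUPs) and a random intercept
#' per scanning group. Inference on fixed effects uses Satterthwaite
#' degrees of freedom with Wald confidence intervals. Partial per-sex trait
#' slopes follow from the contrast coding:
#' `slope(level) = beta_trait + code(level) * beta_interaction`.
#' Singular fits are refitted without the scanning-group term (flagged in
#' the result); the node random slope is never dropped.
#'
#' @param longTable output of [buildLongTable()].
#' @return an `AssociationResult`: tidy `terms` table (estimate, se, df, t,
#'   p, CI), `partial_beta_by_sex`, node `blups`, and the underlying fit.
#' @export
fitModuleModel <- function(longTable) {
  nNodes <- length(unique(longTable$node_id))
  nSub <- length(unique(longTable$subject_id))
  if (nNodes < 2) stop("need at least 2 nodes in the module", call. = FALSE)
  if (nSub < 10) warning("fewer than 10 subjects: estimates unstable")
  rnd <- c("(1 | subject_id)", "(0 + trait_c | node_id)")
  if (length(unique(longTable$scan_group)) >= 2) {
    rnd <- c(rnd, "(1 | scan_group)")
  } else {
    warning("fewer than 2 scanning groups: group term dropped")
  }
  longTable$node_id <- factor(longTable$node_id)
  f <- .fitWithFallback(longTable, rnd)
  .mkResult(f$fit, longTable, f$note, nNodes)
}

#' Anderson-Darling residual screen and refit
#'
#' Implements the second, robustness step of the association framework: an
#' initial fit's residuals are grouped by node, each node's residuals are
#' tested for normality with the Anderson-Darling test, nodes with
#' `p < alpha_ad` are excluded, and the model is refitted on the remaining
#' nodes. Both fits are returned. Nodes with fewer than 8 residuals are
#' retained untested (the test is undefined there).
#'
#' @param longTable output of [buildLongTable()].
#' @param alpha_ad exclusion threshold; `0` disables all exclusions.
#' @return list `initial` (AssociationResult), `screened`
#'   (AssociationResult after exclusions), `excluded` (node ids),
#'   `ad_p` (named vector of per-node p values).
#' @export
residualScreen <- function(longTable, alpha_ad = 0.05) {
  fit0 <- fitModuleModel(longTable)
  r <- stats::residuals(fit0$fit)
  nodes <- as.character(longTable$node_id)
  adp <- vapply(split(r, nodes), function(x) {
    if (length(x) < 8 || stats::sd(x) == 0) return(NA_real_)
    nortest::ad.test(x)$p.value
  }, numeric(1))
  excluded <- names(adp)[!is.na(adp) & adp < alpha_ad]
  if (length(excluded) == length(unique(nodes)))
    stop("residual screen excluded every node; inspect the model residuals",
         call. = FALSE)
  if (!length(excluded)) {
    screened <- fit0
  } else {
    keep <- !(as.character(longTable$node_id) %in% excluded)
    screened <- fitModuleModel(longTable[keep, , drop = FALSE])
    screened$n_excluded <- length(excluded)
  }
  list(initial = fit0, screened = screened,
       excluded = as.integer(excluded), ad_p = adp)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values for a family of p values.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return q values, same length and order as `p`.
#' @export
#' @examples
#' fdrCorrect(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
fdrCorrect <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Cross-resolution multivariate association model
#'
#' The headline estimate for a module detected at several resolutions:
#' the per-gamma long tables are stacked, gamma levels enter as repeated
#' measures (random intercept per gamma), node random slopes are nested
#' within gamma, and the fixed effects are those of [fitModuleModel()]. With
#' a single table the per-gamma model is returned with a warning.
#'
#' @param longTables named list of [buildLongTable()] outputs, names =
#'   gamma values.
#' @return an `AssociationResult`.
#' @export
crossGammaModel <- function(longTables) {
  if (length(longTables) == 1) {
    warning("module available at a single gamma: per-gamma model returned")
    return(fitModuleModel(longTables[[1]]))
  }
  stacked <- do.call(rbind, Map(function(tab, g) {
    tab$gamma_f <- g
    tab
  }, longTables, names(longTables)))
  stacked$gamma_f <- factor(stacked$gamma_f)
  stacked$gnode <- interaction(stacked$gamma_f, stacked$node_id, drop = TRUE)
  nNodes <- length(unique(stacked$node_id))
  rnd <- c("(1 | subject_id)", "(1 | gamma_f)", "(0 + trait_c | gnode)")
  if (length(unique(stacked$scan_group)) >= 2) rnd <- c(rnd,
                                                        "(1 | scan_group)")
  f <- .fitWithFallback(stacked, rnd)
  .mkResult(f$fit, stacked, f$note, nNodes)
}

#' Individual conditional expectation curves
#'
#' Predicted outcome over a grid of trait values for every subject, holding
#' each subject's observed covariates fixed and including the subject's
#' random intercept (node deviations average to zero by shrinkage). Each
#' subject's curve is a line with slope
#' `beta_trait + code(sex) * beta_interaction`.
#'
#' @param result an `AssociationResult`.
#' @param traitGrid numeric grid of (transformed) trait values.
#' @return long data.frame `subject_id, trait, predicted`.
#' @export
iceCurves <- function(result,
                      traitGrid = seq(-2, 2, length.out = 21)) {
  fe <- lme4::fixef(result$fit)
  re <- lme4::ranef(result$fit)
  uSub <- if ("subject_id" %in% names(re))
    stats::setNames(re$subject_id[, 1], rownames(re$subject_id))
  else NULL
  d <- result$data
  subj <- d[!duplicated(d$subject_id),
            c("subject_id", "sex_c", "age_c", "scan_group")]
  out <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
    s <- subj[i, ]
    eta <- fe["(Intercept)"] + fe["trait_c"] * traitGrid +
      fe["sex_c"] * s$sex_c + fe["age_c"] * s$age_c +
      fe["trait_c:sex_c"] * traitGrid * s$sex_c
    if (!is.null(uSub)) eta <- eta + uSub[as.character(s$subject_id)]
    data.frame(subject_id = s$subject_id, trait = traitGrid,
               predicted = as.numeric(eta))
  }))
  rownames(out) <- NULL
  out
}

#' Scan every (module, metric, trait) family at one or more resolutions
#'
#' Runs [buildLongTable()] + [fitModuleModel()] (optionally with the
#' Anderson-Darling residual screen) for each combination and adjusts the
#' trait-effect p values with [fdrCorrect()] within each (gamma, trait)
#' family across modules and metrics.
#'
#' @param metricTable tidy metric table.
#' @param cohort scored cohort.
#' @param modulesByGamma named list (by gamma) of lists of module node-id
#'   vectors (e.g. derived from consensus partitions).
#' @param metrics metric names to model.
#' @param traits cohort trait columns to model (one model per trait).
#' @param screen apply [residualScreen()] before reporting.
#' @param alpha_ad screen threshold.
#' @param minNodes skip modules smaller than this.
#' @return list: `table` — tidy data.frame `gamma, module, metric, trait,
#'   estimate, se, df, t, p, ci_low, ci_high, q, n_nodes, n_excluded`;
#'   `results` — the underlying `AssociationResult`s, and `longTables` for
#'   re-use by [crossGammaModel()].
#' @export
associationScan <- function(metricTable, cohort, modulesByGamma,
                            metrics = c("degree", "betweenness",
                                        "participation"),
                            traits = c("ve_t", "iu_t"),
                            screen = FALSE, alpha_ad = 0.05,
                            minNodes = 2L) {
  rows <- list()
  results <- list()
  longs <- list()
  for (g in names(modulesByGamma)) {
    mods <- modulesByGamma[[g]]
    for (mi in seq_along(mods)) {
      nodes <- mods[[mi]]
      if (length(nodes) < minNodes) next
      for (met in metrics) for (tr in traits) {
        lt <- buildLongTable(metricTable, cohort, as.numeric(g), nodes,
                             metric = met, trait = tr)
        res <- if (screen) residualScreen(lt, alpha_ad)$screened
        else fitModuleModel(lt)
        key <- paste(g, mi, met, tr, sep = "|")
        results[[key]] <- res
        longs[[key]] <- lt
        bt <- res$beta_trait
        rows[[key]] <- data.frame(
          gamma = as.numeric(g), module = mi, metric = met, trait = tr,
          estimate = bt$estimate, se = bt$se, df = bt$df, t = bt$t,
          p = bt$p, ci_low = bt$ci_low, ci_high = bt$ci_high,
          n_nodes = res$n_nodes_used, n_excluded = res$n_excluded)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$q <- NA_real_
  for (g in unique(tab$gamma)) for (tr in unique(tab$trait)) {
    fam <- tab$gamma == g & tab$trait == tr
    tab$q[fam] <- fdrCorrect(tab$p[fam])
  }
  list(table = tab, results = results, longTables = longs)
}

#' Write an association results table / per-node BLUP table
#'
#' @param scan output of [associationScan()] (or its `table` element).
#' @param path CSV path.
#' @export
writeAssociationTable <- function(scan, path) {
  tab <- if (is.data.frame(scan)) scan else scan$table
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
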