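#' Score the 30-item empathy questionnaire
#'
#' The instrument has 30 items rated 1-5. The vicarious experience (VE) score
#' is the sum of the 15 odd-numbered items; the intuitive understanding (IU)
#' score is the sum of the 15 even-numbered items (1-based item numbering).
#' No item is reverse-coded. Each raw score therefore lies in [15, 75].
#'
#' @param items numeric vector of exactly 30 responses, each in 1..5.
#' @return named numeric vector `c(ve_raw = , iu_raw = )`.
#' @export
#' @examples
#' scoreEES(rep(1, 30))              # c(ve_raw = 15, iu_raw = 15)
#' scoreEES(rep(c(1, 5), 15))        # odd items 1, even items 5 -> (15, 75)
scoreEES <- function(items) {
  if (length(items) != 30)
    stop("expected exactly 30 item responses, got ", length(items),
         call. = FALSE)
  bad <- which(is.na(items) | items < 1 | items > 5 | items != round(items))
  if (length(bad))
    stop("missing or out-of-range response at item(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  odd <- seq(1, 29, by = 2)
  c(ve_raw = sum(items[odd]), iu_raw = sum(items[-odd]))
}

# profile log-likelihood of the power-transform parameter
.boxcoxLogLik <- function(lambda, x) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum(log(x))
}

#' Box-Cox power transformation with profile-ML lambda
#'
#' `y = (x^lambda - 1) / lambda` (natural log at lambda = 0). When `lambda`
#' is not supplied it is estimated by profile maximum likelihood: a coarse
#' grid over [-3, 3] brackets the optimum, then [stats::optimize()]
#' (golden-section with parabolic interpolation) refines it to 1e-4.
#'
#' @param x positive numeric vector.
#' @param lambda fixed transformation parameter, or NULL to estimate.
#' @return list `y` (transformed values), `lambda`, `loglik`.
#' @export
#' @examples
#' boxcoxTransform(c(15, 40, 75), lambda = 1)$y  # x - 1
boxcoxTransform <- function(x, lambda = NULL) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("Box-Cox requires strictly positive finite values", call. = FALSE)
  if (is.null(lambda)) {
    grid <- seq(-3, 3, by = 0.1)
    ll <- vapply(grid, .boxcoxLogLik, numeric(1), x = x)
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(.boxcoxLogLik, c(lo, hi), x = x,
                           maximum = TRUE, tol = 1e-4)
    lambda <- opt$maximum
  }
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(y = y, lambda = lambda, loglik = .boxcoxLogLik(lambda, x))
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the sum)`.
#'
#' @param items numeric matrix, subjects in rows, items in columns.
#' @return numeric alpha, or NA (with a warning) if the total score has zero
#'   variance.
#' @export
cronbachAlpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  tot <- stats::var(rowSums(items))
  if (tot == 0) {
    warning("zero-variance total score: alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / tot)
}

#' Descriptive behavioral statistics of a scored cohort
#'
#' Reports, per subscale: Cronbach's alpha; the Pearson correlation between
#' the two subscale scores with a Fisher-z confidence interval; and pooled-
#' variance two-sample t-tests (df = n - 2) contrasting females vs males,
#' with confidence intervals for the female - male mean difference.
#'
#' @param cohort data.frame with columns `item_01..item_30`, `sex`
#'   (female/male), `ve_raw`, `iu_raw` (see [generateCohort()],
#'   [scoreCohort()]).
#' @param conf confidence level.
#' @return list with elements `alpha` (ve, iu), `subscale_cor` (r, ci, t, p),
#'   and `sex_contrast` (per subscale: mean_f, mean_m, t, df, p, ci).
#' @export
behavioralDescriptives <- function(cohort, conf = 0.95) {
  itemCols <- sprintf("item_%02d", 1:30)
  items <- as.matrix(cohort[, itemCols])
  odd <- seq(1, 29, by = 2)
  alpha <- c(ve = cronbachAlpha(items[, odd]),
             iu = cronbachAlpha(items[, -odd]))
  n <- nrow(cohort)
  r <- stats::cor(cohort$ve_raw, cohort$iu_raw)
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  zci <- atanh(r) + c(-1, 1) * zcrit / sqrt(n - 3)
  tr <- r * sqrt((n - 2) / (1 - r^2))
  cor_p <- 2 * stats::pt(-abs(tr), df = n - 2)
  pooledT <- function(y) {
    f <- y[cohort$sex == "female"]
    m <- y[cohort$sex == "male"]
    nf <- length(f); nm <- length(m)
    sp2 <- ((nf - 1) * stats::var(f) + (nm - 1) * stats::var(m)) /
      (nf + nm - 2)
    se <- sqrt(sp2 * (1 / nf + 1 / nm))
    d <- mean(f) - mean(m)
    t <- d / se
    df <- nf + nm - 2
    tcrit <- stats::qt(1 - (1 - conf) / 2, df)
    list(mean_f = mean(f), mean_m = mean(m), t = t, df = df,
         p = 2 * stats::pt(-abs(t), df), ci = d + c(-1, 1) * tcrit * se)
  }
  list(alpha = alpha,
       subscale_cor = list(r = r, ci = tanh(zci), t = tr, p = cor_p, n = n),
       sex_contrast = list(ve = pooledT(cohort$ve_raw),
                           iu = pooledT(cohort$iu_raw)))
}

#' Score every subject of a cohort table and attach transformed traits
#'
#' Applies [scoreEES()] per row, fits a Box-Cox transformation separately per
#' subscale, and (by default) standardises the transformed scores to mean 0,
#' SD 1 so downstream regression slopes have stable per-SD units.
#'
#' @param cohort data.frame with `item_01..item_30` columns.
#' @param standardize standardise the transformed scores.
#' @return the cohort with columns `ve_raw, iu_raw, ve_t, iu_t` added and
#'   attributes `lambda_ve`, `lambda_iu`.
#' @export
scoreCohort <- function(cohort, standardize = TRUE) {
  itemCols <- sprintf("item_%02d", 1:30)
  sc <- t(apply(as.matrix(cohort[, itemCols]), 1, scoreEES))
  cohort$ve_raw <- sc[, "ve_raw"]
  cohort$iu_raw <- sc[, "iu_raw"]
  bve <- boxcoxTransform(cohort$ve_raw)
  biu <- boxcoxTransform(cohort$iu_raw)
  std <- function(y) if (standardize) as.numeric(scale(y)) else y
  cohort$ve_t <- std(bve$y)
  cohort$iu_t <- std(biu$y)
  attr(cohort, "lambda_ve") <- bve$lambda
  attr(cohort, "lambda_iu") <- biu$lambda
  cohort
}

#' Read / write a subject table
#'
#' One row per subject with columns `subject_id, sex, age, scan_group,
#' item_01..item_30` (plus derived scores if present).
#'
#' @param cohort data.frame.
#' @param path CSV path.
#' @export
writeSubjectTable <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSubjectTable
#' @export
readSubjectTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
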