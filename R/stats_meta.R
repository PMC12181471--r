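# Per-cohort association models and classical inverse-variance
# meta-analysis (fixed effect, DerSimonian-Laird random effect, Cochran Q /
# I2 heterogeneity). The formulas are implemented directly; confidence
# intervals and p-values use normal quantiles.

#' Association between a score and a predictor within one cohort
#'
#' Ordinary least squares of `outcome` on `predictor` plus covariates
#' (complete cases), reporting the predictor term. One model is fitted per
#' predictor — e.g. one cell-type fraction at a time, since all 12 fractions
#' jointly are collinear on the simplex.
#'
#' @param outcome Numeric vector (e.g. EAA or an inflammation score).
#' @param predictor Numeric vector (e.g. one cell-type fraction).
#' @param covariates Optional per-sample covariate matrix/data frame.
#' @param cohort Cohort label stored in the result.
#' @param term Name of the predictor stored in the result.
#' @return One-row data frame: `cohort`, `term`, `effect`, `se`, `tstat`,
#'   `pvalue`, `n`.
#' @export
linear_assoc <- function(outcome, predictor, covariates = NULL,
                         cohort = NA_character_, term = "predictor") {
  stopifnot(length(outcome) == length(predictor))
  keep <- !is.na(outcome) & !is.na(predictor)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    keep <- keep & complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  outcome <- outcome[keep]
  predictor <- predictor[keep]
  if (var(predictor) == 0) stop("zero predictor variance")
  X <- .design_matrix(predictor, covariates, length(outcome))
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 2) stop("need n > number of model parameters + 2")
  fit <- lm.fit(X, outcome)
  s2 <- sum(fit$residuals^2) / (n - p)
  Cmat <- chol2inv(chol(crossprod(X)))
  effect <- unname(fit$coefficients[2])
  se <- sqrt(s2 * Cmat[2, 2])
  tstat <- effect / se
  data.frame(cohort = cohort, term = term, effect = effect, se = se,
             tstat = tstat,
             pvalue = pmax(.pfloor, 2 * pt(abs(tstat), n - p, lower.tail = FALSE)),
             n = n, stringsAsFactors = FALSE)
}

.check_meta_input <- function(effects, ses, min_k = 1) {
  stopifnot(length(effects) == length(ses))
  if (any(is.na(effects)) || any(is.na(ses))) stop("NA in effects or ses")
  if (any(ses <= 0)) stop("all standard errors must be > 0")
  if (length(effects) < min_k)
    stop("need at least ", min_k, " studies")
  invisible(TRUE)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study effects with weights `1/se^2`; the pooled standard error is
#' `1/sqrt(sum(w))` and the p-value is two-sided normal.
#'
#' @param effects Numeric vector of study effect sizes.
#' @param ses Matching standard errors (> 0).
#' @return List: `effect`, `se`, `z`, `p`, `k`.
#' @export
meta_fixed <- function(effects, ses) {
  .check_meta_input(effects, ses, 1)
  w <- 1 / ses^2
  effect <- sum(w * effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- effect / se
  list(effect = effect, se = se, z = z,
       p = pmax(.pfloor, 2 * pnorm(abs(z), lower.tail = FALSE)),
       k = length(effects))
}

#' Cochran heterogeneity statistics
#'
#' `Q = sum w_i (e_i - pooled)^2` about the fixed-effect pooled estimate,
#' with `df = k - 1`, a chi-square p-value, and
#' `I2 = max(0, (Q - df)/Q) * 100` (0 when Q = 0).
#'
#' @inheritParams meta_fixed
#' @return List: `Q`, `df`, `het_p`, `I2` (percent).
#' @export
heterogeneity <- function(effects, ses) {
  .check_meta_input(effects, ses, 2)
  w <- 1 / ses^2
  pooled <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - pooled)^2)
  df <- length(effects) - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df, het_p = pchisq(Q, df, lower.tail = FALSE), I2 = I2)
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Between-study variance `tau2 = max(0, (Q - df) / (sum(w) -
#' sum(w^2)/sum(w)))` with fixed-effect weights `w = 1/se^2`; the pooled
#' estimate then uses weights `1/(se^2 + tau2)`. When `Q <= df` the estimate
#' collapses to the fixed-effect result.
#'
#' @inheritParams meta_fixed
#' @return List: `effect`, `se`, `z`, `p`, `tau2`, `k`.
#' @export
meta_random <- function(effects, ses) {
  .check_meta_input(effects, ses, 2)
  het <- heterogeneity(effects, ses)
  w <- 1 / ses^2
  tau2 <- max(0, (het$Q - het$df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  effect <- sum(wr * effects) / sum(wr)
  se <- 1 / sqrt(sum(wr))
  z <- effect / se
  list(effect = effect, se = se, z = z,
       p = pmax(.pfloor, 2 * pnorm(abs(z), lower.tail = FALSE)),
       tau2 = tau2, k = length(effects))
}

#' Full meta-analysis summary for one term
#'
#' Combines [meta_fixed()], [meta_random()] and [heterogeneity()] into the
#' one-row summary used by forest plots.
#'
#' @param effects,ses Study effects and standard errors (k >= 2).
#' @param term Term label.
#' @return One-row data frame: `term`, `k`, `fixed_effect`, `fixed_se`,
#'   `fixed_p`, `random_effect`, `random_se`, `random_p`, `tau2`, `Q`, `df`,
#'   `het_p`, `I2`.
#' @export
meta_summary <- function(effects, ses, term = "term") {
  fx <- meta_fixed(effects, ses)
  rd <- meta_random(effects, ses)
  ht <- heterogeneity(effects, ses)
  data.frame(term = term, k = fx$k,
             fixed_effect = fx$effect, fixed_se = fx$se, fixed_p = fx$p,
             random_effect = rd$effect, random_se = rd$se, random_p = rd$p,
             tau2 = rd$tau2, Q = ht$Q, df = ht$df, het_p = ht$het_p,
             I2 = ht$I2, stringsAsFactors = FALSE)
}

#' Per-cohort fraction associations pooled by meta-analysis
#'
#' For every cell type, regresses a per-sample score on that cell type's
#' estimated fraction within each cohort (adjusting for the given sample
#' sheet covariates) and pools the per-cohort effects by fixed- and
#' random-effects inverse-variance meta-analysis. Regressions of age
#' acceleration on fractions conventionally adjust for sex; inflammation
#' score regressions adjust for age and sex.
#'
#' @param scores Data frame with columns `sample_id`, `cohort` and the
#'   `outcome` column (e.g. from [score_table()]).
#' @param fractions Named list of [fraction_matrix()], one per cohort.
#' @param samples A [sample_sheet()] covering all cohorts.
#' @param outcome Name of the score column to regress (e.g. `"eaa"`).
#' @param adjust Sample-sheet columns used as covariates (e.g. `"sex"` or
#'   `c("age", "sex")`).
#' @return List with `per_cohort` (stacked [linear_assoc()] rows) and
#'   `meta` (one [meta_summary()] row per cell type).
#' @export
meta_fraction_assoc <- function(scores, fractions, samples, outcome,
                                adjust = "sex") {
  stopifnot(outcome %in% names(scores))
  cohort_ids <- names(fractions)
  per <- list()
  for (id in cohort_ids) {
    fm <- fractions[[id]]
    sc <- scores[scores$cohort == id, ]
    sh <- as.data.frame(samples)[match(sc$sample_id, samples$sample_id), ]
    fmv <- unclass(fm)[sc$sample_id, , drop = FALSE]
    covs <- if (length(adjust)) as.matrix(sh[, adjust, drop = FALSE]) else NULL
    for (ct in colnames(fmv)) {
      per[[length(per) + 1]] <- linear_assoc(
        sc[[outcome]], fmv[, ct], covariates = covs, cohort = id, term = ct)
    }
  }
  per <- do.call(rbind, per)
  meta <- do.call(rbind, lapply(split(per, per$term), function(d)
    meta_summary(d$effect, d$se, term = d$term[1])))
  rownames(meta) <- NULL
  list(per_cohort = per, meta = meta)
}
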