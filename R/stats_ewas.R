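# Per-CpG association testing. The workhorse is a vectorized OLS across all
# CpGs sharing one design matrix; CpGs with missing betas fall back to a
# per-CpG complete-case fit.

.pfloor <- 1e-300  # avoid -log10 underflow in volcano exports

.design_matrix <- function(outcome, covariates, n) {
  X <- cbind(`(Intercept)` = rep(1, n), outcome = outcome)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Per-CpG univariate regression
#'
#' For every CpG, fits ordinary least squares of the beta value on an
#' outcome plus optional covariates, and reports the outcome term's effect
#' (delta beta per unit outcome), standard error, t statistic and two-sided
#' p-value (t distribution, residual degrees of freedom).
#'
#' @param bm A [beta_matrix()] (CpGs x samples).
#' @param outcome Numeric vector, one value per sample.
#' @param covariates Optional numeric matrix/data frame of per-sample
#'   covariates.
#' @return Data frame with one row per CpG: `cpg_id`, `effect`, `se`,
#'   `tstat`, `pvalue`, `neglog10p`, `n`.
#' @export
univariate_cpg_regression <- function(bm, outcome, covariates = NULL) {
  stopifnot(inherits(bm, "beta_matrix"))
  Y <- unclass(bm)
  n <- ncol(Y)
  stopifnot(length(outcome) == n)
  keep <- !is.na(outcome)
  if (!is.null(covariates)) keep <- keep & complete.cases(as.matrix(covariates))
  Y <- Y[, keep, drop = FALSE]
  X <- .design_matrix(outcome[keep],
                      if (is.null(covariates)) NULL else
                        as.matrix(covariates)[keep, , drop = FALSE],
                      sum(keep))
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 2) stop("need n > number of model parameters + 2")
  Cmat <- chol2inv(chol(crossprod(X)))
  df <- n - p
  run_rows <- function(Yr) {
    B <- (Yr %*% X) %*% Cmat                 # m x p coefficients
    resid <- Yr - B %*% t(X)
    sigma2 <- rowSums(resid^2) / df
    se <- sqrt(sigma2 * Cmat[2, 2])
    list(effect = B[, 2], se = se)
  }
  full <- !apply(is.na(Y), 1, any)
  effect <- se <- rep(NA_real_, nrow(Y))
  nn <- rep(n, nrow(Y))
  if (any(full)) {
    r <- run_rows(Y[full, , drop = FALSE])
    effect[full] <- r$effect
    se[full] <- r$se
  }
  for (j in which(!full)) {                   # complete-case fallback
    ok <- !is.na(Y[j, ])
    if (sum(ok) <= p + 2) next
    f <- lm.fit(X[ok, , drop = FALSE], Y[j, ok])
    s2 <- sum(f$residuals^2) / (sum(ok) - p)
    Cj <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))
    effect[j] <- f$coefficients[2]
    se[j] <- sqrt(s2 * Cj[2, 2])
    nn[j] <- sum(ok)
  }
  tstat <- effect / se
  pvalue <- pmax(.pfloor, 2 * pt(abs(tstat), nn - p, lower.tail = FALSE))
  data.frame(cpg_id = rownames(Y), effect = effect, se = se, tstat = tstat,
             pvalue = pvalue, neglog10p = -log10(pvalue), n = nn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Epigenome-wide association study with optional cell-fraction adjustment
#'
#' Regresses each CpG's beta value on a binary condition plus covariates.
#' When a fraction matrix is supplied, the estimated cell-type fractions are
#' added as covariates — with one cell type dropped (by default the one with
#' the largest mean fraction, neutrophils in blood) to break the sum-to-one
#' collinearity. CpGs with `pvalue < alpha / m` (Bonferroni across the m
#' CpGs tested) are flagged as DMCs.
#'
#' @param bm A [beta_matrix()].
#' @param condition Binary 0/1 vector, one per sample.
#' @param covariates Optional per-sample covariate matrix.
#' @param adjust_fractions Optional [fraction_matrix()] (samples in the same
#'   order as `bm` columns) used as additional covariates.
#' @param alpha Family-wise significance level (default 0.05).
#' @param drop_cell_type Cell type dropped from the fraction covariates;
#'   default the largest mean fraction.
#' @return An `ewas_result` data frame (per-CpG `effect`, `se`, `tstat`,
#'   `pvalue`, `neglog10p`, `dmc_flag`) with attribute
#'   `bonferroni_threshold`.
#' @export
ewas <- function(bm, condition, covariates = NULL, adjust_fractions = NULL,
                 alpha = 0.05, drop_cell_type = NULL) {
  condition <- as.numeric(condition)
  if (any(!condition %in% c(0, 1), na.rm = TRUE))
    stop("condition must be binary 0/1")
  if (min(table(condition)) < 3)
    stop("each condition group needs at least 3 samples")
  if (!is.null(adjust_fractions)) {
    stopifnot(inherits(adjust_fractions, "fraction_matrix"))
    Fm <- unclass(adjust_fractions)
    if (nrow(Fm) != ncol(bm))
      stop("fraction matrix samples do not match beta matrix")
    if (is.null(drop_cell_type))
      drop_cell_type <- colnames(Fm)[which.max(colMeans(Fm, na.rm = TRUE))]
    if (!drop_cell_type %in% colnames(Fm))
      stop("unknown cell type: ", drop_cell_type)
    Fm <- Fm[, setdiff(colnames(Fm), drop_cell_type), drop = FALSE]
    covariates <- if (is.null(covariates)) Fm else cbind(as.matrix(covariates), Fm)
  }
  res <- univariate_cpg_regression(bm, condition, covariates)
  m <- nrow(res)
  thr <- alpha / m
  res$dmc_flag <- !is.na(res$pvalue) & res$pvalue < thr
  attr(res, "bonferroni_threshold") <- thr
  attr(res, "dropped_cell_type") <- drop_cell_type
  class(res) <- c("ewas_result", "data.frame")
  res
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum test between the two groups of `groups`:
#' exact when the smaller group has at most 25 observations and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param values Numeric vector.
#' @param groups Vector with exactly two distinct levels, same length.
#' @return List with `statistic` (rank-sum W of the first group), `p_value`,
#'   `exact` (logical) and the two group sizes.
#' @export
wilcoxon_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- groups[ok]
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("groups must have exactly two non-empty levels")
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (!length(x) || !length(y)) stop("one group is empty")
  exact <- min(length(x), length(y)) <= 25 && !anyDuplicated(values)
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact, n1 = length(x), n2 = length(y))
}
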