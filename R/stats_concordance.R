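# Multivariate-vs-univariate coefficient concordance: a penalized
# multivariate predictor's selected CpGs should agree in sign with their
# univariate associations. Exact one-tailed Fisher test on the 2x2 sign
# table plus Pearson correlation of the coefficient vectors.

#' One-tailed Fisher exact test on a 2x2 table
#'
#' Conditional on both margins, the `[1,1]` count follows a hypergeometric
#' distribution; the one-tailed p-value is the upper tail `P(X >= a)`
#' (`direction = "greater"`, positive association) or the lower tail
#' (`direction = "less"`).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param direction `"greater"` (default) or `"less"`.
#' @return The one-tailed p-value.
#' @export
fisher_one_tailed <- function(table, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold non-negative integer counts")
  if (sum(table) == 0) stop("all-zero table")
  a <- table[1, 1]
  r1 <- sum(table[1, ])
  c1 <- sum(table[, 1])
  N <- sum(table)
  if (direction == "greater")
    phyper(a - 1, c1, N - c1, r1, lower.tail = FALSE)
  else
    phyper(a, c1, N - c1, r1, lower.tail = TRUE)
}

#' Sign concordance between multivariate and univariate coefficients
#'
#' Drops CpGs with a zero multivariate coefficient (not selected by the
#' penalized model), cross-tabulates the signs of the remaining pairs,
#' tests for positive sign association with a one-tailed Fisher exact test,
#' and correlates the two coefficient vectors (Pearson, two-sided p).
#' Pairs whose univariate coefficient is exactly zero carry no sign and are
#' excluded from the table (they remain in the correlation).
#'
#' @param multi_coefs Multivariate (e.g. elastic net) coefficients.
#' @param uni_coefs Matching univariate regression coefficients.
#' @return A `concordance_result` list: `table` (2x2, rows = multivariate
#'   sign +/-, cols = univariate sign +/-), `n_concordant`, `n_discordant`,
#'   `fisher_p`, `pearson_r`, `pearson_p`, `n_used`.
#' @export
sign_concordance <- function(multi_coefs, uni_coefs) {
  stopifnot(length(multi_coefs) == length(uni_coefs))
  keep <- !is.na(multi_coefs) & !is.na(uni_coefs) & multi_coefs != 0
  m <- multi_coefs[keep]
  u <- uni_coefs[keep]
  if (length(m) < 3) stop("fewer than 3 non-zero coefficient pairs")
  signed <- u != 0
  tab <- matrix(c(sum(m > 0 & u > 0), sum(m > 0 & u < 0),
                  sum(m < 0 & u > 0), sum(m < 0 & u < 0)),
                2, 2, byrow = TRUE,
                dimnames = list(multi = c("pos", "neg"),
                                uni = c("pos", "neg")))
  ct <- suppressWarnings(stats::cor.test(m, u, method = "pearson"))
  structure(list(
    table = tab,
    n_concordant = tab[1, 1] + tab[2, 2],
    n_discordant = tab[1, 2] + tab[2, 1],
    fisher_p = fisher_one_tailed(tab, "greater"),
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
    n_used = sum(signed)), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "sign concordance: %d concordant / %d discordant (Fisher p = %.3g, r = %.3f)\n",
    x$n_concordant, x$n_discordant, x$fisher_p, x$pearson_r))
  invisible(x)
}

#' Elastic net fit at a single penalty
#'
#' Minimizes `(1/(2n)) * loss + lambda * (alpha_mix * sum|beta| +
#' (1 - alpha_mix)/2 * sum(beta^2))` with squared-error (`gaussian`) or
#' negative log-likelihood (`binomial`) loss. Predictors are standardized
#' internally; coefficients are returned on the original scale. The
#' unpenalized limit `lambda = 0` is computed exactly by ordinary least
#' squares / unpenalized logistic regression.
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Outcome vector (0/1 for `binomial`).
#' @param alpha_mix L1/L2 mixing parameter in `[0, 1]` (1 = lasso).
#' @param lambda Penalty strength (>= 0).
#' @param family `"gaussian"` or `"binomial"`.
#' @return List: `intercept`, `coefficients` (named, original scale),
#'   `lambda`, `alpha_mix`.
#' @export
elastic_net_fit <- function(X, y, alpha_mix = 0.5, lambda,
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (lambda < 0) stop("lambda must be >= 0")
  stopifnot(alpha_mix >= 0, alpha_mix <= 1)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (lambda == 0) {
    if (family == "gaussian") {
      fit <- lm.fit(cbind(1, X), y)
      b <- fit$coefficients
    } else {
      fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
      b <- fit$coefficients
    }
    return(list(intercept = unname(b[1]),
                coefficients = setNames(unname(b[-1]), colnames(X)),
                lambda = 0, alpha_mix = alpha_mix))
  }
  # decreasing lambda path ending at the requested value, so the coefficient
  # at that value is solved (not interpolated)
  n <- nrow(X)
  yc <- if (family == "gaussian") y - mean(y) else y - mean(y)
  Xs <- scale(X, scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
  lmax <- max(abs(crossprod(Xs, yc)) / n) / max(alpha_mix, 1e-3)
  lmax <- max(lmax, lambda * 1.01)
  path <- sort(unique(c(exp(seq(log(lmax), log(max(lambda, lmax * 1e-4)),
                                length.out = 60)), lambda)),
               decreasing = TRUE)
  p <- ncol(X)
  Xfit <- if (p == 1) cbind(X, .pad = 0) else X  # solver needs >= 2 columns
  fit <- glmnet::glmnet(Xfit, y, family = family, alpha = alpha_mix,
                        lambda = path, standardize = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  i <- which.min(abs(fit$lambda - lambda))
  b <- c(unname(fit$a0[i]), as.numeric(fit$beta[, i]))
  list(intercept = b[1],
       coefficients = setNames(b[1 + seq_len(p)], colnames(X)),
       lambda = lambda, alpha_mix = alpha_mix)
}
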