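# Reference-based cell-type deconvolution. Two estimators share the same
# contract (fractions in [0,1], sum 1 after renormalization):
#   - CLS: constrained least squares, w >= 0 with sum(w) = 1 or <= 1,
#     solved as an NNLS problem (Lawson-Hanson via pracma::lsqnonneg) with
#     the sum constraint imposed through a heavily weighted equality row
#     plus, for the inequality, a slack variable.
#   - RPC: robust partial correlations — a Huber M-estimator regression of
#     the sample profile on the reference (IRLS, MAD scale), negative
#     coefficients truncated to zero, then renormalized — the estimator
#     blood methylation studies conventionally use.

.aligned_ref <- function(bm, panel) {
  stopifnot(inherits(bm, "beta_matrix"), inherits(panel, "reference_panel"))
  shared <- intersect(rownames(panel), rownames(bm))
  if (length(shared) < ncol(panel))
    stop("underdetermined: only ", length(shared),
         " marker CpGs shared between data and panel (need >= ",
         ncol(panel), ")")
  R <- unclass(panel)[shared, , drop = FALSE]
  Y <- unclass(align_features(bm, shared, "strict")$beta)
  list(R = R, Y = Y)
}

# min ||y - R w||^2  s.t.  w >= 0 and sum(w) {=,<=} 1.
# The equality is enforced by appending the row  M * 1' w = M  to the least
# squares system with M >> 1; for the inequality a non-negative slack s is
# added so that sum(w) + s = 1. At the optimum of a consistent system the
# penalty row is satisfied exactly; otherwise the violation is O(1/M^2).
.cls_one <- function(y, R, constraint, M = 1e3) {
  K <- ncol(R)
  if (constraint == "sum_eq_1") {
    A <- rbind(R, M)
    b <- c(y, M)
  } else {
    A <- rbind(cbind(R, 0), M)
    b <- c(y, M)
  }
  w <- tryCatch(pracma::lsqnonneg(A, b)$x,
                error = function(e) .nnls_active_set(A, b))
  w[seq_len(K)]
}

# Lawson-Hanson active-set NNLS with a generous iteration budget; used when
# the library routine exceeds its fixed iteration cap on the augmented
# (penalty-row) system.
.nnls_active_set <- function(A, b, tol = 1e-10, maxit = NULL) {
  n <- ncol(A)
  if (is.null(maxit)) maxit <- 100 * n
  passive <- logical(n)
  x <- numeric(n)
  for (it in seq_len(maxit)) {
    g <- crossprod(A, b - A %*% x)[, 1]
    cand <- which(!passive & g > tol)
    if (!length(cand)) break
    passive[cand[which.max(g[cand])]] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      viol <- passive & z <= tol
      alpha <- min(x[viol] / (x[viol] - z[viol]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

#' Estimate cell fractions by constrained least squares
#'
#' Per sample, finds the non-negative weight vector minimizing the squared
#' error between the observed profile and the mixed reference profiles,
#' subject to the weights summing to 1 (`sum_eq_1`) or at most 1
#' (`sum_le_1`). CpGs are matched by id (strict alignment on the shared
#' set); samples with missing values at shared CpGs use their complete CpGs
#' only.
#'
#' @param bm A [beta_matrix()].
#' @param panel A [reference_panel()]; at least K shared marker CpGs
#'   required.
#' @param constraint `"sum_le_1"` (default) or `"sum_eq_1"`.
#' @param renormalize Divide each weight vector by its sum (when positive)
#'   so fractions sum to 1. Default `TRUE`.
#' @return A [fraction_matrix()] (samples x cell types).
#' @export
estimate_fractions_cls <- function(bm, panel,
                                   constraint = c("sum_le_1", "sum_eq_1"),
                                   renormalize = TRUE) {
  constraint <- match.arg(constraint)
  al <- .aligned_ref(bm, panel)
  K <- ncol(al$R)
  n <- ncol(al$Y)
  W <- matrix(NA_real_, n, K, dimnames = list(colnames(al$Y), colnames(al$R)))
  conv <- rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- al$Y[, i]
    ok <- !is.na(y)
    if (sum(ok) < K) stop("sample ", colnames(al$Y)[i],
                          " has fewer non-NA marker CpGs than cell types")
    w <- .cls_one(y[ok], al$R[ok, , drop = FALSE], constraint)
    if (renormalize && sum(w) > 0) w <- w / sum(w)
    W[i, ] <- pmin(1, pmax(0, w))
    conv[i] <- TRUE
  }
  fraction_matrix(W, converged = conv)
}

#' Estimate cell fractions by robust partial correlations (RPC)
#'
#' Per sample, fits a Huber M-estimator linear regression (IRLS with MAD
#' scale, tuning constant `huber_c`, at most `maxit` iterations) of the
#' observed profile on the reference profiles, truncates negative
#' coefficients to zero and renormalizes to proportions. Robust weighting
#' down-weights CpGs whose methylation departs from the mixture model
#' (outliers, cell-type-specific disease effects), which plain least squares
#' cannot do.
#'
#' @param bm A [beta_matrix()].
#' @param panel A [reference_panel()].
#' @param maxit Maximum IRLS iterations (default 500).
#' @param huber_c Huber tuning constant (default 1.345, the classical 95%
#'   Gaussian-efficiency value).
#' @return A [fraction_matrix()]; samples whose coefficients are all
#'   non-positive are returned as all-`NA` rows with `converged = FALSE`.
#' @export
estimate_fractions_rpc <- function(bm, panel, maxit = 500, huber_c = 1.345) {
  al <- .aligned_ref(bm, panel)
  K <- ncol(al$R)
  n <- ncol(al$Y)
  W <- matrix(NA_real_, n, K, dimnames = list(colnames(al$Y), colnames(al$R)))
  conv <- rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- al$Y[, i]
    ok <- !is.na(y)
    if (sum(ok) < K + 1) stop("sample ", colnames(al$Y)[i],
                              " has too few non-NA marker CpGs")
    fit <- suppressWarnings(
      MASS::rlm(x = cbind(`(Intercept)` = 1, al$R[ok, , drop = FALSE]),
                y = y[ok], psi = MASS::psi.huber, k = huber_c,
                scale.est = "MAD", maxit = maxit, acc = 1e-8))
    w <- coef(fit)[-1]
    if (all(w <= 0)) next  # flagged failure: all-NA row
    w[w < 0] <- 0
    W[i, ] <- w / sum(w)
    conv[i] <- fit$converged
  }
  fraction_matrix(W, converged = conv)
}

#' Total lymphocyte fraction
#'
#' Sum of the B, T, Treg and NK fractions — the denominator of the
#' neutrophil-to-lymphocyte ratio.
#'
#' @param fm A [fraction_matrix()] containing all of [lymphocyte_types()].
#' @return Named numeric vector, one value per sample.
#' @export
lymphocyte_fraction <- function(fm) {
  stopifnot(inherits(fm, "fraction_matrix"))
  need <- lymphocyte_types()
  miss <- setdiff(need, colnames(fm))
  if (length(miss))
    stop("fraction matrix missing lymphocyte type(s): ",
         paste(miss, collapse = ", "))
  rowSums(unclass(fm)[, need, drop = FALSE])
}

#' Composition ratio between cell-type fractions
#'
#' Per-sample ratio of one cell type's fraction to another's (or to the
#' lymphocyte aggregate), with the denominator floored to avoid division by
#' zero. `composition_ratio(fm, "Neu", "lymphocytes")` is the
#' neutrophil-to-lymphocyte ratio; `composition_ratio(fm, "Neu", "CD8Tmem")`
#' the neutrophil to memory CD8+ T-cell ratio.
#'
#' @param fm A [fraction_matrix()].
#' @param numerator Cell-type name.
#' @param denominator Cell-type name or `"lymphocytes"`.
#' @param floor Lower bound applied to the denominator (default 1e-6).
#' @return Named numeric vector, one ratio per sample.
#' @export
composition_ratio <- function(fm, numerator, denominator = "lymphocytes",
                              floor = 1e-6) {
  stopifnot(inherits(fm, "fraction_matrix"))
  if (!numerator %in% colnames(fm))
    stop("unknown cell type: ", numerator)
  num <- unclass(fm)[, numerator]
  den <- if (identical(denominator, "lymphocytes")) {
    lymphocyte_fraction(fm)
  } else {
    if (!denominator %in% colnames(fm))
      stop("unknown cell type: ", denominator)
    unclass(fm)[, denominator]
  }
  num / pmax(den, floor)
}
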