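# Rectified linear clocks, extrinsic age acceleration and the signed
# signature inflammation score.

#' Rectify clock CpGs
#'
#' For every clock CpG flagged for rectification (a hypermethylated age-DMC
#' whose methylation decreases under inflammation) the beta value is mapped
#' to `1 - beta`, so that an all-positive-coefficient clock accumulates age
#' and inflammation effects in the same direction. Applying the map twice
#' restores the original matrix.
#'
#' @param bm A [beta_matrix()] aligned to the clock CpGs.
#' @param clock A [clock_definition()].
#' @return A [beta_matrix()] with flagged rows replaced by `1 - beta`.
#' @export
rectify_betas <- function(bm, clock) {
  stopifnot(inherits(bm, "beta_matrix"), inherits(clock, "clock_definition"))
  v <- unclass(bm)
  flag <- clock$entries$cpg_id[clock$entries$rectify]
  flag <- intersect(flag, rownames(v))
  v[flag, ] <- 1 - v[flag, ]
  beta_matrix(v)
}

#' Apply a linear clock to a beta matrix
#'
#' Computes, per sample, `intercept + sum_j coefficient_j * beta_j` over the
#' clock CpGs, with flagged CpGs rectified to `1 - beta` first when
#' `rectify = TRUE`. CpGs absent from the data are handled by the alignment
#' `policy` (see [align_features()]).
#'
#' @param bm A [beta_matrix()].
#' @param clock A [clock_definition()].
#' @param rectify Apply the rectification flags (default `TRUE`).
#' @param policy Alignment policy for missing clock CpGs.
#' @return Named numeric vector of DNAm ages (years), one per sample.
#' @export
apply_clock <- function(bm, clock, rectify = TRUE,
                        policy = c("strict", "impute_mean")) {
  policy <- match.arg(policy)
  stopifnot(inherits(clock, "clock_definition"))
  cpgs <- clock$entries$cpg_id
  if (!any(cpgs %in% rownames(bm)))
    stop("none of the clock CpGs are present in the data")
  al <- align_features(bm, cpgs, policy)
  v <- unclass(al$beta)
  if (rectify) v <- unclass(rectify_betas(al$beta, clock))
  drop(clock$intercept + crossprod(v, clock$entries$coefficient)[, 1])
}

#' Extrinsic age acceleration
#'
#' Residuals of the ordinary least squares regression of DNAm age on
#' chronological age (with intercept). Samples with a missing age get an
#' `NA` residual. Fit one cohort at a time: pooling cohorts lets batch
#' offsets masquerade as age acceleration.
#'
#' @param dnam_age Numeric vector of clock ages (years).
#' @param chron_age Numeric vector of chronological ages (years).
#' @return Numeric vector of residuals (years), mean 0 and uncorrelated with
#'   `chron_age` over the non-`NA` samples.
#' @export
compute_eaa <- function(dnam_age, chron_age) {
  stopifnot(length(dnam_age) == length(chron_age))
  ok <- !is.na(dnam_age) & !is.na(chron_age)
  if (sum(ok) < 3) stop("need at least 3 samples with non-NA ages")
  if (var(chron_age[ok]) == 0) stop("age variance zero")
  fit <- lm.fit(cbind(1, chron_age[ok]), dnam_age[ok])
  out <- rep(NA_real_, length(dnam_age))
  out[ok] <- fit$residuals
  names(out) <- names(dnam_age)
  out
}

#' Z-score a beta matrix CpG-wise
#'
#' Centers and scales every CpG row to mean 0 and sample (n-1 denominator)
#' standard deviation 1 across the samples of one cohort. Zero-variance rows
#' cannot be scaled; they are dropped from the result and their ids recorded
#' in the `dropped` attribute.
#'
#' @param bm A [beta_matrix()] for a single cohort (>= 2 samples).
#' @return Numeric matrix of z-scores with attribute `dropped`.
#' @export
zscore_by_cpg <- function(bm) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (ncol(bm) < 2) stop("z-scoring needs at least 2 samples")
  v <- unclass(bm)
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  keep <- !is.na(s) & s > 0
  z <- (v[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(z, "dropped") <- rownames(v)[!keep]
  z
}

#' Signed-signature inflammation score
#'
#' Per sample, the Pearson correlation between the sample's z-scored
#' methylation profile and the signature's ±1 sign vector over the CpGs the
#' two share. A z-profile that rises exactly where the signature says the
#' phenotype raises methylation scores +1; the mirror profile scores -1.
#'
#' @param z A z-score matrix from [zscore_by_cpg()] (CpGs x samples).
#' @param sig A [signature_definition()]; at least 3 of its CpGs must be
#'   present in `z`.
#' @return Named numeric vector of scores in `[-1, 1]` with attribute
#'   `coverage` (fraction of signature CpGs found). A sample whose z-vector
#'   has zero variance gets `NA` with a warning.
#' @export
infl_score <- function(z, sig) {
  stopifnot(is.matrix(z), inherits(sig, "signature_definition"))
  idx <- match(sig$entries$cpg_id, rownames(z))
  found <- !is.na(idx)
  if (sum(found) < 3)
    stop("fewer than 3 signature CpGs overlap the z-matrix")
  coverage <- mean(found)
  zz <- z[idx[found], , drop = FALSE]
  s <- sig$entries$sign[found]
  scores <- vapply(seq_len(ncol(zz)), function(i) {
    zi <- zz[, i]
    if (sd(zi) == 0) return(NA_real_)
    cor(zi, s)
  }, numeric(1))
  if (anyNA(scores))
    warning(sum(is.na(scores)), " sample(s) with zero-variance z-vector; NA score")
  names(scores) <- colnames(zz)
  attr(scores, "coverage") <- coverage
  scores
}

#' Score a multi-cohort study: DNAm age, EAA and inflammation score
#'
#' Convenience wrapper running [apply_clock()], per-cohort [compute_eaa()],
#' per-cohort [zscore_by_cpg()] and [infl_score()] over a list of cohorts.
#'
#' @param cohorts Named list with elements `beta` and `samples` per cohort
#'   (as produced by [simulate_multi_cohort()]).
#' @param clock A [clock_definition()] (optional).
#' @param sig A [signature_definition()] (optional).
#' @param policy Alignment policy for missing CpGs.
#' @return Data frame with columns `sample_id`, `cohort`, `dnam_age`, `eaa`,
#'   `infl_score` (columns present only when the matching definition was
#'   given).
#' @export
score_table <- function(cohorts, clock = NULL, sig = NULL,
                        policy = c("strict", "impute_mean")) {
  policy <- match.arg(policy)
  out <- lapply(names(cohorts), function(id) {
    co <- cohorts[[id]]
    df <- data.frame(sample_id = co$samples$sample_id, cohort = id,
                     stringsAsFactors = FALSE)
    if (!is.null(clock)) {
      df$dnam_age <- apply_clock(co$beta, clock, rectify = TRUE, policy = policy)
      df$eaa <- compute_eaa(df$dnam_age, co$samples$age)
    }
    if (!is.null(sig)) {
      z <- zscore_by_cpg(co$beta)
      df$infl_score <- infl_score(z, sig)[df$sample_id]
    }
    df
  })
  do.call(rbind, out)
}
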