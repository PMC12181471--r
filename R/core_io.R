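# Domain containers. All are light S3 wrappers over base matrices and data
# frames, validated at construction. Orientation convention throughout:
# CpGs are rows, samples are columns (Illumina convention).

#' Construct a validated beta-value matrix
#'
#' A `beta_matrix` is a numeric CpG-by-sample matrix of methylation fractions
#' in `[0, 1]`, with unique CpG row names and unique sample column names.
#' `NA` entries are permitted.
#'
#' @param values Numeric matrix, CpGs in rows, samples in columns.
#' @param cpg_ids,sample_ids Optional character vectors overriding dimnames.
#' @return A `beta_matrix` object (a classed matrix).
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cpg_ids) || is.null(sample_ids))
    stop("beta_matrix requires cpg_ids (rownames) and sample_ids (colnames)")
  if (length(cpg_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  rownames(values) <- as.character(cpg_ids)
  colnames(values) <- as.character(sample_ids)
  .check_unique(rownames(values), "cpg_id")
  .check_unique(colnames(values), "sample_id")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad))
    stop("beta out of range [0,1] at ", length(bad), " cell(s), first: ",
         rownames(values)[(bad[1] - 1) %% nrow(values) + 1])
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples (%.1f%% NA)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

.check_unique <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d))
    stop("duplicate ", what, ": ", paste(head(d, 5), collapse = ", "))
  invisible(TRUE)
}

#' Construct a validated sample sheet
#'
#' Per-sample phenotypes: `sample_id`, `age` (years, `NA` allowed), `sex`
#' (0/1), `condition` (0 = control, 1 = case), `cohort` label, plus any
#' additional numeric covariate columns.
#'
#' @param df Data frame with at least the five mandatory columns.
#' @return A `sample_sheet` (a classed data frame).
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "condition", "cohort")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$cohort <- as.character(df$cohort)
  .check_unique(df$sample_id, "sample_id")
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$age) & df$age < 0)) stop("age must be >= 0")
  for (col in c("sex", "condition")) {
    v <- df[[col]]
    if (is.character(v) && col == "sex")
      v <- c(F = 0, M = 1)[v]  # documented mapping: F -> 0, M -> 1
    v <- as.numeric(v)
    if (any(!v %in% c(0, 1), na.rm = TRUE))
      stop("unknown ", col, " code: must be 0/1",
           if (col == "sex") " (or F/M)")
    df[[col]] <- v
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Construct a validated cell-type reference panel
#'
#' Marker-CpG-by-cell-type matrix of reference beta values in `[0, 1]`.
#' Rows may carry an `is_marker` attribute distinguishing cell-type marker
#' CpGs from non-discriminative background CpGs.
#'
#' @param values Numeric matrix, marker CpGs in rows, cell types in columns.
#' @param is_marker Optional logical vector, one entry per row.
#' @return A `reference_panel` object.
#' @export
reference_panel <- function(values, is_marker = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("reference panel requires cpg_id rownames and cell-type colnames")
  .check_unique(rownames(values), "cpg_id")
  .check_unique(colnames(values), "cell_type")
  if (any(is.na(values)) || any(values < 0 | values > 1))
    stop("reference beta values must be in [0,1] with no NA")
  if (!is.null(is_marker)) {
    stopifnot(length(is_marker) == nrow(values), is.logical(is_marker))
    attr(values, "is_marker") <- is_marker
  }
  structure(values, class = c("reference_panel", "matrix", "array"))
}

#' Subset a reference panel to its marker CpGs
#'
#' @param panel A [reference_panel()].
#' @return The panel restricted to rows flagged as markers (all rows when no
#'   flag is present).
#' @export
marker_panel <- function(panel) {
  m <- attr(panel, "is_marker")
  if (is.null(m)) return(panel)
  reference_panel(unclass(panel)[m, , drop = FALSE])
}

#' Construct a validated fraction matrix
#'
#' Sample-by-cell-type estimated (or true) proportions. Values lie in
#' `[0, 1]`; per-sample sums must not exceed 1 beyond numerical tolerance
#' (renormalized estimates sum to 1). Rows of all-`NA` mark samples whose
#' estimation failed; a per-sample `converged` attribute records solver
#' status.
#'
#' @param values Numeric matrix, samples in rows, cell types in columns.
#' @param converged Optional logical vector, one per sample.
#' @return A `fraction_matrix` object.
#' @export
fraction_matrix <- function(values, converged = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("fraction matrix requires sample_id rownames and cell-type colnames")
  .check_unique(rownames(values), "sample_id")
  .check_unique(colnames(values), "cell_type")
  ok <- !apply(is.na(values), 1, all)
  v <- values[ok, , drop = FALSE]
  if (any(v < -1e-8 | v > 1 + 1e-8, na.rm = TRUE))
    stop("fractions must lie in [0,1]")
  s <- rowSums(v)
  if (any(s > 1 + 1e-6))
    stop("per-sample fraction sums exceed 1")
  if (is.null(converged)) converged <- ok
  stopifnot(length(converged) == nrow(values))
  structure(values, converged = converged,
            class = c("fraction_matrix", "matrix", "array"))
}

#' Construct a linear clock definition
#'
#' A clock is an intercept (years) plus per-CpG coefficients (years per beta
#' unit). Each entry carries a rectification flag: `TRUE` means the CpG is a
#' hypermethylated age-DMC whose methylation decreases under inflammation, so
#' the clock is applied to `1 - beta` at that CpG.
#'
#' @param entries Data frame with columns `cpg_id`, `coefficient`, `rectify`.
#' @param intercept Clock intercept in years.
#' @param all_positive Require all coefficients > 0 (the convention for
#'   rectified inflammation clocks). Default `FALSE`.
#' @return A `clock_definition` object.
#' @export
clock_definition <- function(entries, intercept, all_positive = FALSE) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("cpg_id", "coefficient", "rectify")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("clock definition missing column(s): ", paste(miss, collapse = ", "))
  entries$cpg_id <- as.character(entries$cpg_id)
  .check_unique(entries$cpg_id, "cpg_id")
  entries$coefficient <- as.numeric(entries$coefficient)
  entries$rectify <- as.logical(entries$rectify)
  if (any(!is.finite(entries$coefficient)))
    stop("clock coefficients must be finite")
  if (any(is.na(entries$rectify))) stop("rectify flags must be TRUE/FALSE (1/0)")
  if (all_positive && any(entries$coefficient <= 0))
    stop("all coefficients must be > 0 for a rectified inflammation clock")
  intercept <- as.numeric(intercept)
  stopifnot(length(intercept) == 1, is.finite(intercept))
  structure(list(intercept = intercept, entries = entries[, need]),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("clock_definition: %d CpGs, intercept %.4g years, %d rectified\n",
              nrow(x$entries), x$intercept, sum(x$entries$rectify)))
  invisible(x)
}

#' Construct a signed CpG signature
#'
#' A signature is a set of CpGs each carrying the sign (+1 / -1) of its
#' effect on the phenotype the signature proxies (e.g. serum CRP level).
#'
#' @param entries Data frame with columns `cpg_id`, `sign`.
#' @return A `signature_definition` object.
#' @export
signature_definition <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  miss <- setdiff(c("cpg_id", "sign"), names(entries))
  if (length(miss))
    stop("signature missing column(s): ", paste(miss, collapse = ", "))
  entries$cpg_id <- as.character(entries$cpg_id)
  .check_unique(entries$cpg_id, "cpg_id")
  entries$sign <- as.numeric(entries$sign)
  if (any(!entries$sign %in% c(-1, 1)))
    stop("sign must be ±1")
  structure(list(entries = entries[, c("cpg_id", "sign")]),
            class = "signature_definition")
}

#' Restrict a beta matrix to a requested CpG set
#'
#' Aligns rows of `bm` to `wanted`, in that order. Under the `strict` policy
#' any missing CpG is an error; under `impute_mean` missing CpGs are filled
#' with the maximally uninformative beta 0.5 and the achieved coverage is
#' reported (a warning is emitted below 80% coverage).
#'
#' @param bm A [beta_matrix()].
#' @param wanted Character vector of CpG ids (non-empty).
#' @param policy `"strict"` (default) or `"impute_mean"`.
#' @return List with `beta` (the aligned [beta_matrix()]) and `coverage`
#'   (fraction of `wanted` found in `bm`).
#' @export
align_features <- function(bm, wanted, policy = c("strict", "impute_mean")) {
  policy <- match.arg(policy)
  stopifnot(inherits(bm, "beta_matrix"))
  wanted <- as.character(wanted)
  if (!length(wanted)) stop("wanted CpG set is empty")
  .check_unique(wanted, "wanted cpg_id")
  present <- wanted %in% rownames(bm)
  coverage <- mean(present)
  if (policy == "strict" && !all(present))
    stop("missing CpG(s) under strict alignment: ",
         paste(head(wanted[!present], 5), collapse = ", "),
         if (sum(!present) > 5) sprintf(" (+%d more)", sum(!present) - 5))
  out <- matrix(0.5, nrow = length(wanted), ncol = ncol(bm),
                dimnames = list(wanted, colnames(bm)))
  out[present, ] <- unclass(bm)[wanted[present], , drop = FALSE]
  if (coverage < 0.8)
    warning(sprintf("feature coverage %.1f%% below 80%%", 100 * coverage))
  list(beta = beta_matrix(out), coverage = coverage)
}
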