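# Plain-text readers/writers for the five tabular formats. All are id-keyed
# CSV/TSV; "NA" or an empty cell denotes missing on read, "NA" on write.

.sep_for <- function(dialect) {
  switch(match.arg(dialect, c("csv", "tsv")), csv = ",", tsv = "\t")
}

.read_table <- function(path, sep) {
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE,
           na.strings = c("NA", ""), comment.char = "#")
}

.numeric_cells <- function(df, what) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("non-numeric cell in ", what, " at row ", bad[1],
             ", column '", names(df)[j], "': '", v[bad[1]], "'")
      df[[j]] <- num
    }
  }
  df
}

#' Read a beta-value matrix from CSV/TSV
#'
#' Expects the first column to hold CpG ids and the header row sample ids.
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, dialect = c("csv", "tsv")) {
  df <- .read_table(path, .sep_for(dialect))
  if (ncol(df) < 2) stop("beta matrix file needs an id column plus samples")
  ids <- as.character(df[[1]])
  df <- .numeric_cells(df[-1], "beta matrix")
  m <- as.matrix(df)
  rownames(m) <- ids
  beta_matrix(m)
}

#' Write a beta-value matrix to CSV/TSV
#'
#' @param bm A [beta_matrix()].
#' @param path Output path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(bm, "beta_matrix"))
  df <- data.frame(cpg_id = rownames(bm), unclass(bm), check.names = FALSE)
  write.table(df, path, sep = .sep_for(dialect), row.names = FALSE,
              quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Columns: `sample_id,age,sex,condition,cohort` plus optional extra numeric
#' covariates. Sex may be coded 0/1 or F/M (F maps to 0, M to 1).
#'
#' @param path File path.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(.read_table(path, ","))
}

#' Write a sample sheet to CSV
#' @param ss A [sample_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(ss, path) {
  stopifnot(inherits(ss, "sample_sheet"))
  write.csv(as.data.frame(ss), path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a cell-type reference panel from CSV
#'
#' Header row: `cpg_id,<cell types...>`. An optional trailing logical column
#' `is_marker` distinguishes marker from background CpGs.
#'
#' @param path File path.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  df <- .read_table(path, ",")
  if (ncol(df) < 3) stop("reference panel needs cpg_id plus >= 2 cell types")
  ids <- as.character(df[[1]])
  df <- df[-1]
  is_marker <- NULL
  if ("is_marker" %in% names(df)) {
    is_marker <- as.logical(df$is_marker)
    df$is_marker <- NULL
  }
  m <- as.matrix(.numeric_cells(df, "reference panel"))
  rownames(m) <- ids
  reference_panel(m, is_marker = is_marker)
}

#' Write a cell-type reference panel to CSV
#' @param panel A [reference_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  df <- data.frame(cpg_id = rownames(panel), unclass(panel),
                   check.names = FALSE)
  m <- attr(panel, "is_marker")
  if (!is.null(m)) df$is_marker <- m
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a clock definition from CSV
#'
#' Body columns: `cpg_id,coefficient,rectify` (rectify coded 0/1 or
#' TRUE/FALSE). The intercept travels in a leading comment line
#' `#intercept=<years>`.
#'
#' @param path File path.
#' @param all_positive Passed to [clock_definition()].
#' @return A [clock_definition()].
#' @export
read_clock_definition <- function(path, all_positive = FALSE) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#intercept=", first))
    stop("clock file must start with a '#intercept=<x>' line")
  intercept <- as.numeric(sub("^#intercept=", "", first))
  if (is.na(intercept)) stop("could not parse clock intercept from: ", first)
  df <- .read_table(path, ",")
  df$rectify <- as.logical(as.numeric(df$rectify))
  clock_definition(df, intercept = intercept, all_positive = all_positive)
}

#' Write a clock definition to CSV
#' @param clock A [clock_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_definition <- function(clock, path) {
  stopifnot(inherits(clock, "clock_definition"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#intercept=%.17g", clock$intercept), con)
  df <- clock$entries
  df$rectify <- as.integer(df$rectify)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a signed CpG signature from CSV
#'
#' Columns: `cpg_id,sign` with sign in {-1, +1}.
#'
#' @param path File path.
#' @return A [signature_definition()].
#' @export
read_signature <- function(path) {
  signature_definition(.read_table(path, ","))
}

#' Write a signed CpG signature to CSV
#' @param sig A [signature_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_definition"))
  write.csv(sig$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fraction matrix from CSV
#'
#' Header row: `sample_id,<cell types...>`; samples in rows.
#'
#' @param path File path.
#' @return A [fraction_matrix()].
#' @export
read_fraction_matrix <- function(path) {
  df <- .read_table(path, ",")
  ids <- as.character(df[[1]])
  m <- as.matrix(.numeric_cells(df[-1], "fraction matrix"))
  rownames(m) <- ids
  fraction_matrix(m)
}

#' Write a fraction matrix to CSV
#' @param fm A [fraction_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fraction_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "fraction_matrix"))
  df <- data.frame(sample_id = rownames(fm), unclass(fm), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
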