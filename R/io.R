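# Readers and writers for the package's plain-text formats:
#   * expression / GI50 matrices: TSV or CSV, first column = row ids,
#     header = column ids, "NA" for missing;
#   * signatures: TSV with "# treatment=" and "# threshold=" header lines;
#   * clinical tables: CSV with fixed named columns.

#' Read a features x samples expression matrix
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return validated numeric matrix (see [expression_matrix()]); `"NA"`
#'   cells are stored as missing values, never as zero.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv")) {
  m <- .read_matrix(path, match.arg(dialect))
  expression_matrix(m)
}

#' Write an expression matrix
#' @param mat features x samples matrix.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_expression_matrix <- function(mat, path, dialect = c("tsv", "csv")) {
  .write_matrix(mat, path, match.arg(dialect), "feature_id")
}

#' Read a drug-sensitivity (GI50) table
#'
#' Rows are drugs, columns are cell lines. Values are stored uniformly on
#' the -log10(GI50) scale: molar inputs are transformed, `neg_log10` inputs
#' pass through unchanged.
#'
#' @param path file path (TSV).
#' @param scale `"neg_log10"` (default, the scale the NCI DTP distributes)
#'   or `"gi50_molar"`.
#' @return validated drug-response panel (see [drug_response_panel()]).
#' @export
read_gi50_table <- function(path, scale = c("neg_log10", "gi50_molar")) {
  scale <- match.arg(scale)
  m <- .read_matrix(path, "tsv")
  if (scale == "gi50_molar") {
    if (any(m <= 0, na.rm = TRUE))
      stop("molar GI50 values must be positive (log10 undefined)")
    m <- -log10(m)
  }
  drug_response_panel(m)
}

#' Write a drug-response panel (as -log10(GI50))
#' @param panel drugs x cell lines matrix.
#' @param path output path (TSV).
#' @export
write_gi50_table <- function(panel, path) {
  .write_matrix(panel, path, "tsv", "drug")
}

#' Read a clinical table
#'
#' CSV with columns `patient_id`, `ipi`, `treatment`, `response`,
#' `os_days`, `os_event`, `pfs_days`, `pfs_event`, `relapse`,
#' `relapse_regimens` (semicolon-separated). Response labels are matched
#' case-insensitively against [RESPONSE_CATEGORIES].
#'
#' @param path file path.
#' @return validated `patient_records` data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  patient_records(df)
}

#' Write a clinical table
#' @param records `patient_records` data.frame.
#' @param path output path (CSV).
#' @export
write_clinical_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a response signature
#'
#' TSV with leading comment lines `# treatment=<name>` and
#' `# threshold=<value>` followed by a header row with at least
#' `feature_id` and `selection_correlation` columns (extra columns are
#' preserved as annotation).
#'
#' @param path file path.
#' @return a [response_signature()].
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(hit)) stop("signature file missing '# ", key, "=' header line")
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1]))
  }
  treatment <- get_field("treatment")
  threshold <- as.numeric(get_field("threshold"))
  if (is.na(threshold)) stop("signature threshold header is not numeric")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("feature_id", "selection_correlation") %in% names(df)))
    stop("signature file must have feature_id and selection_correlation columns")
  response_signature(treatment, df, threshold)
}

#' Write a response signature
#'
#' Round-trips with [read_signature()]: writing then reading reproduces the
#' entries exactly at the stored precision.
#'
#' @param signature a [response_signature()].
#' @param path output path (TSV).
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "response_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# treatment=", signature$treatment_name),
               paste0("# threshold=", format(signature$threshold, digits = 15))),
             con)
  utils::write.table(signature$entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged 20-feature CHOP response signature
#'
#' The published CHOP signature: 20 microRNA/snoRNA probe-set ids with their
#' single-agent in-vitro correlations (vincristine, doxorubicin,
#' cyclophosphamide) and in-vivo remission correlations. The
#' `selection_correlation` column stores each feature's strongest
#' single-agent correlation as a surrogate, because the correlation against
#' the summed three-drug sensitivity vector used at selection was not
#' published; the surrogate exceeds the 0.25 threshold for all 20 features.
#'
#' @return a [response_signature()] with 20 entries.
#' @export
chop_signature <- function() {
  path <- system.file("extdata", "chop_signature.tsv", package = "mirsens",
                      mustWork = TRUE)
  read_signature(path)
}

#' Align an expression matrix with a clinical table
#'
#' Intersects expression sample ids with clinical patient ids, returning the
#' overlap in cohort (clinical) order and reporting what was dropped on each
#' side.
#'
#' @param expr features x samples matrix.
#' @param clinical `patient_records` data.frame.
#' @return list with `expr` (columns reordered to the shared ids),
#'   `clinical` (matching rows), `dropped_samples`, `dropped_patients`.
#' @export
align_cohort <- function(expr, clinical) {
  keep <- clinical$patient_id %in% colnames(expr)
  common <- clinical$patient_id[keep]
  if (!length(common))
    stop("expression samples and clinical patients do not overlap")
  list(expr = expr[, common, drop = FALSE],
       clinical = clinical[keep, , drop = FALSE],
       dropped_samples = setdiff(colnames(expr), common),
       dropped_patients = clinical$patient_id[!keep])
}

# ---- internal ---------------------------------------------------------

.read_matrix <- function(path, dialect) {
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("matrix file needs an id column plus data columns")
  ids <- df[[1]]
  .check_ids(ids, nrow(df), "row")
  .check_ids(colnames(df)[-1], ncol(df) - 1, "column")
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(vals) & !is.na(raw) &
    !(toupper(trimws(raw)) %in% c("NA", "NAN", ""))
  if (any(bad)) {
    loc <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric value '", raw[loc[1], loc[2]], "' at row '",
         ids[loc[1]], "', column '", colnames(df)[-1][loc[2]], "'")
  }
  dimnames(vals) <- list(ids, colnames(df)[-1])
  vals
}

.write_matrix <- function(mat, path, dialect, id_col) {
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
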