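# Core data types. Expression matrices and drug-response panels are plain
# numeric matrices (features/drugs in rows, samples/cell lines in columns)
# validated by their constructors; signatures and clinical tables carry S3
# classes.

#' Recognized clinical response categories
#'
#' Ordered worst-to-best for display; the ordinal coding used in analyses is
#' defined by [response_coding()]. "Dead" means dead before response
#' evaluation; "Unevaluable" records are excluded from response analyses.
#'
#' @export
RESPONSE_CATEGORIES <- c("CR", "CRu", "PR", "SD", "PD", "Dead", "Unevaluable")

#' Construct a validated log2 expression matrix
#'
#' @param values numeric matrix, features x samples. Missing values (`NA`)
#'   are allowed; present values must be finite.
#' @param feature_ids,sample_ids identifiers; default to the dimnames of
#'   `values`. Must be unique and non-empty.
#' @return the matrix with dimnames set, invisibly classed as a plain matrix.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  .check_ids(feature_ids, nrow(values), "feature")
  .check_ids(sample_ids, ncol(values), "sample")
  if (any(!is.finite(values) & !is.na(values)))
    stop("expression values must be finite where present")
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

#' Construct a validated drug-response panel
#'
#' Stores per-drug sensitivity vectors over a shared set of cell lines on
#' the -log10(GI50) scale (higher = more sensitive).
#'
#' @param values numeric matrix, drugs x cell lines, -log10(GI50).
#' @param drug_names,cell_line_ids identifiers; default to dimnames.
#' @return the validated matrix.
#' @export
drug_response_panel <- function(values, drug_names = rownames(values),
                                cell_line_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("GI50 values must be numeric")
  .check_ids(drug_names, nrow(values), "drug")
  .check_ids(cell_line_ids, ncol(values), "cell line")
  if (any(!is.finite(values) & !is.na(values)))
    stop("-log10(GI50) values must be finite where present")
  n_ok <- rowSums(!is.na(values))
  if (any(n_ok < 3))
    stop("drug(s) with fewer than 3 non-missing cell lines: ",
         paste(drug_names[n_ok < 3], collapse = ", "))
  dimnames(values) <- list(drug_names, cell_line_ids)
  values
}

#' Construct a treatment response signature
#'
#' A named treatment's selected feature list with the Pearson correlation
#' each feature showed against the treatment's summed -log10(GI50)
#' sensitivity vector, and the selection threshold used.
#'
#' @param treatment_name regimen label, e.g. `"CHOP"`.
#' @param entries data.frame with columns `feature_id` and
#'   `selection_correlation` (extra columns are preserved).
#' @param threshold Pearson cutoff used at selection (default 0.25). Every
#'   entry must have `selection_correlation > threshold`.
#' @return object of class `response_signature`.
#' @export
response_signature <- function(treatment_name, entries, threshold = 0.25) {
  stopifnot(is.character(treatment_name), length(treatment_name) == 1,
            nzchar(treatment_name), is.data.frame(entries))
  if (!all(c("feature_id", "selection_correlation") %in% names(entries)))
    stop("entries must have columns feature_id and selection_correlation")
  if (nrow(entries) == 0) stop("signature must contain at least one feature")
  entries$feature_id <- as.character(entries$feature_id)
  dup <- entries$feature_id[duplicated(entries$feature_id)]
  if (length(dup)) stop("duplicate signature feature(s): ",
                        paste(unique(dup), collapse = ", "))
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold))
    stop("threshold must be a single finite number")
  bad <- entries$selection_correlation <= threshold
  if (any(is.na(bad)) || any(bad))
    stop("every selection_correlation must exceed the threshold (",
         threshold, "); offending feature(s): ",
         paste(entries$feature_id[is.na(bad) | bad], collapse = ", "))
  rownames(entries) <- NULL
  structure(list(treatment_name = treatment_name, entries = entries,
                 threshold = threshold),
            class = "response_signature")
}

#' @export
print.response_signature <- function(x, ...) {
  cat(sprintf("Response signature '%s': %d feature(s), threshold r > %g\n",
              x$treatment_name, nrow(x$entries), x$threshold))
  print(utils::head(x$entries, 10), row.names = FALSE)
  if (nrow(x$entries) > 10) cat("... and", nrow(x$entries) - 10, "more\n")
  invisible(x)
}

#' Feature identifiers of a signature
#' @param signature a [response_signature()].
#' @return character vector of feature ids.
#' @export
signature_features <- function(signature) {
  stopifnot(inherits(signature, "response_signature"))
  signature$entries$feature_id
}

#' Construct a GCB/ABC subtype profile
#'
#' Two disjoint, non-empty microRNA lists; the subtype score of a sample is
#' mean(GCB features) - mean(ABC features).
#'
#' @param gcb_features,abc_features character vectors of feature ids.
#' @return object of class `subtype_profile`.
#' @export
subtype_profile <- function(gcb_features, abc_features) {
  gcb_features <- as.character(gcb_features)
  abc_features <- as.character(abc_features)
  if (!length(gcb_features) || !length(abc_features))
    stop("both feature lists must be non-empty")
  if (anyDuplicated(gcb_features) || anyDuplicated(abc_features))
    stop("feature lists must not contain duplicates")
  if (length(intersect(gcb_features, abc_features)))
    stop("GCB and ABC feature lists must be disjoint")
  structure(list(gcb_features = gcb_features, abc_features = abc_features),
            class = "subtype_profile")
}

#' Validate a clinical table of patient records
#'
#' Checks the invariants of the per-patient clinical record: unique patient
#' ids, IPI in 0..5, response among [RESPONSE_CATEGORIES] (matched
#' case-insensitively), non-negative survival times, logical event flags,
#' and `pfs_days <= os_days` whenever both events are recorded.
#'
#' @param df data.frame with columns `patient_id`, `ipi`, `treatment`,
#'   `response`, `os_days`, `os_event`, `pfs_days`, `pfs_event`, `relapse`,
#'   `relapse_regimens` (semicolon-separated labels, possibly empty).
#' @return the validated data.frame, classed `patient_records`.
#' @export
patient_records <- function(df) {
  req <- c("patient_id", "ipi", "treatment", "response", "os_days",
           "os_event", "pfs_days", "pfs_event", "relapse", "relapse_regimens")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing clinical column(s): ",
                         paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup)) stop("duplicate patient id(s): ",
                        paste(unique(dup), collapse = ", "))
  if (any(is.na(df$ipi)) || any(df$ipi != as.integer(df$ipi)) ||
      any(df$ipi < 0 | df$ipi > 5))
    stop("ipi must be an integer in 0..5")
  df$ipi <- as.integer(df$ipi)
  idx <- match(toupper(as.character(df$response)), toupper(RESPONSE_CATEGORIES))
  if (any(is.na(idx)))
    stop("unknown response label(s): ",
         paste(unique(df$response[is.na(idx)]), collapse = ", "),
         "; allowed: ", paste(RESPONSE_CATEGORIES, collapse = ", "))
  df$response <- RESPONSE_CATEGORIES[idx]
  for (col in c("os_days", "pfs_days")) {
    if (!is.numeric(df[[col]]) || any(is.na(df[[col]])) || any(df[[col]] < 0))
      stop(col, " must be non-negative and non-missing")
  }
  for (col in c("os_event", "pfs_event", "relapse"))
    df[[col]] <- .as_flag(df[[col]], col)
  both <- df$os_event & df$pfs_event
  bad <- both & df$pfs_days > df$os_days
  if (any(bad))
    stop("pfs_days exceeds os_days with both events recorded for patient(s): ",
         paste(df$patient_id[bad], collapse = ", "))
  df$relapse_regimens <- ifelse(is.na(df$relapse_regimens), "",
                                as.character(df$relapse_regimens))
  class(df) <- unique(c("patient_records", class(df)))
  df
}

#' Split semicolon-separated relapse regimen labels
#' @param x character vector as stored in the clinical table.
#' @return list of character vectors (empty vector for no regimens).
#' @export
split_regimens <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Assemble a per-patient score set
#'
#' @param patient_id,raw,normalized,combined equal-length vectors.
#' @param cutoff classification cutoff applied to the normalized score.
#' @return data.frame classed `score_set` with columns `patient_id`, `raw`,
#'   `normalized`, `combined`, `call`; the cutoff is kept as an attribute.
#' @export
score_set <- function(patient_id, raw, normalized, combined, cutoff = 50) {
  n <- length(patient_id)
  stopifnot(length(raw) == n, length(normalized) == n, length(combined) == n)
  if (n >= 2 && length(unique(raw)) >= 2) {
    rng <- range(normalized)
    if (abs(rng[1]) > 1e-8 || abs(rng[2] - 100) > 1e-8)
      stop("normalized scores must span exactly [0, 100]")
  }
  out <- data.frame(patient_id = as.character(patient_id), raw = raw,
                    normalized = normalized, combined = combined,
                    call = classify(normalized, cutoff),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- unique(c("score_set", class(out)))
  out
}

# ---- internal helpers -------------------------------------------------

.check_ids <- function(ids, n, what) {
  if (is.null(ids)) stop(what, " identifiers are required")
  if (length(ids) != n)
    stop("number of ", what, " identifiers (", length(ids),
         ") does not match matrix dimension (", n, ")")
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop(what, " identifiers must be non-missing and non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate ", what, " identifier(s): ",
         paste(unique(dup), collapse = ", "))
  invisible(TRUE)
}

.as_flag <- function(x, col) {
  if (is.logical(x)) {
    if (any(is.na(x))) stop(col, " must be non-missing")
    return(x)
  }
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1")] <- TRUE
  out[v %in% c("FALSE", "F", "0")] <- FALSE
  if (any(is.na(out)))
    stop(col, " must be logical (TRUE/FALSE or 0/1); offending value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}
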