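# Signature construction: sum the component drugs' -log10(GI50) vectors
# over cell lines, correlate every expression feature with the summed
# vector, and keep features whose Pearson r exceeds the threshold.

#' Summed sensitivity vector of a drug combination
#'
#' The per-drug -log10(GI50) vectors of the combination's components are
#' summed, unweighted and without standardization. A cell line is retained
#' only if it has a non-missing value for every component drug.
#'
#' @param panel drugs x cell lines matrix of -log10(GI50)
#'   (see [drug_response_panel()]).
#' @param component_drugs character vector of drug labels, all present in
#'   the panel.
#' @return named numeric vector over the retained cell lines.
#' @export
combination_sensitivity_vector <- function(panel, component_drugs) {
  component_drugs <- as.character(component_drugs)
  if (!length(component_drugs)) stop("at least one component drug required")
  missing_drugs <- setdiff(component_drugs, rownames(panel))
  if (length(missing_drugs))
    stop("drug(s) not in panel: ", paste(missing_drugs, collapse = ", "))
  sub <- panel[component_drugs, , drop = FALSE]
  keep <- colSums(is.na(sub)) == 0
  if (sum(keep) < 3)
    stop("fewer than 3 cell lines with complete data across all component ",
         "drugs; correlation would be meaningless")
  colSums(sub[, keep, drop = FALSE])
}

#' Per-feature Pearson correlation with a sensitivity vector
#'
#' Correlates each expression feature with the sensitivity vector over the
#' cell lines common to both, using pairwise-complete observations. Features
#' with zero variance (or fewer than 3 complete pairs) get an undefined
#' correlation and are marked excluded. Two-sided p-values come from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param expr features x cell lines log2 expression matrix.
#' @param sens named sensitivity vector (e.g. from
#'   [combination_sensitivity_vector()]).
#' @return data.frame with columns `feature_id`, `r`, `n`, `p`, `excluded`.
#' @export
feature_correlations <- function(expr, sens) {
  if (is.null(names(sens))) stop("sensitivity vector must be named")
  common <- intersect(colnames(expr), names(sens))
  if (length(common) < 3)
    stop("fewer than 3 cell lines shared between expression and sensitivity")
  E <- expr[, common, drop = FALSE]
  s <- sens[common]
  r <- suppressWarnings(as.vector(stats::cor(t(E), s,
                                             use = "pairwise.complete.obs")))
  n <- as.integer(rowSums(!is.na(E) & rep(!is.na(s), each = nrow(E))))
  excluded <- is.na(r) | n < 3
  r[excluded] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- ifelse(is.na(r), NA_real_,
              ifelse(abs(r) >= 1, 0,
                     2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)))
  data.frame(feature_id = rownames(expr), r = r, n = n, p = p,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Select signature features above a correlation threshold
#'
#' Keeps features whose correlation is strictly greater than the threshold
#' ("above"); ties at the threshold are excluded and negatively correlated
#' features are never selected. Entries are sorted by feature id for
#' determinism.
#'
#' @param correlations data.frame from [feature_correlations()].
#' @param threshold positive Pearson cutoff (default 0.25).
#' @param treatment_name label stored in the signature.
#' @return a [response_signature()].
#' @export
select_signature <- function(correlations, threshold = 0.25,
                             treatment_name = "treatment") {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  keep <- !correlations$excluded & !is.na(correlations$r) &
    correlations$r > threshold
  if (!any(keep))
    stop("no feature has correlation above ", threshold,
         "; review the threshold or the input panel")
  sel <- correlations[keep, , drop = FALSE]
  sel <- sel[order(sel$feature_id), , drop = FALSE]
  entries <- data.frame(feature_id = sel$feature_id,
                        selection_correlation = sel$r,
                        n = sel$n, p = sel$p, stringsAsFactors = FALSE)
  response_signature(treatment_name, entries, threshold)
}

#' Build a drug-combination response signature from a cell-line panel
#'
#' Composition of [combination_sensitivity_vector()],
#' [feature_correlations()] and [select_signature()]; deterministic given
#' its inputs.
#'
#' @param panel drugs x cell lines -log10(GI50) matrix.
#' @param expr features x cell lines log2 expression matrix.
#' @param component_drugs drugs making up the combination.
#' @param treatment_name regimen label (e.g. `"CHOP"`).
#' @param threshold Pearson cutoff (default 0.25).
#' @return a [response_signature()].
#' @export
build_signature <- function(panel, expr, component_drugs, treatment_name,
                            threshold = 0.25) {
  sens <- combination_sensitivity_vector(panel, component_drugs)
  cors <- feature_correlations(expr, sens)
  select_signature(cors, threshold = threshold,
                   treatment_name = treatment_name)
}
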