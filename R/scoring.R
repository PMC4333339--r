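# Patient scoring: equal-weight mean of the signature features, linear
# 0-100 rescaling over the cohort, combination with the IPI, GCB/ABC
# subtype scores, and a quantile-normalization utility for raw intensities.

#' Raw prediction score: equal-weight mean of signature features
#'
#' Each signature feature is given equal weight; the raw score of a sample
#' is the unweighted mean of the signature features' expression values. A
#' sample missing some signature-feature values is scored as the mean over
#' the non-missing ones, with a warning.
#'
#' @param expr features x samples matrix, or a named vector for one sample.
#' @param signature a [response_signature()].
#' @return named numeric vector of raw scores, one per sample.
#' @export
raw_prediction_score <- function(expr, signature) {
  stopifnot(inherits(signature, "response_signature"))
  if (!is.matrix(expr)) {
    if (is.null(names(expr))) stop("single-sample expression must be named")
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "sample"))
  }
  feats <- signature_features(signature)
  present <- intersect(feats, rownames(expr))
  if (!length(present))
    stop("none of the ", length(feats), " signature features are present ",
         "in the expression matrix")
  if (length(present) < length(feats))
    warning(length(feats) - length(present), " signature feature(s) absent ",
            "from the expression matrix; scoring uses the ",
            length(present), " present")
  sub <- expr[present, , drop = FALSE]
  if (anyNA(sub))
    warning("missing signature-feature values; per-sample mean taken over ",
            "non-missing features")
  out <- colMeans(sub, na.rm = TRUE)
  if (anyNA(out) || any(is.nan(out)))
    stop("sample(s) with no non-missing signature-feature values: ",
         paste(colnames(sub)[is.nan(out) | is.na(out)], collapse = ", "))
  out
}

#' Linear 0-100 normalization of raw scores
#'
#' `s' = 100 * (s - min) / (max - min)` over the scored cohort: the minimum
#' maps to 0 and the maximum to 100.
#'
#' @param raw numeric vector with at least two distinct values.
#' @return normalized scores on the 0-100 scale.
#' @export
normalize_scores <- function(raw) {
  if (length(raw) < 2) stop("need at least 2 raw scores to normalize")
  if (anyNA(raw)) stop("raw scores must be non-missing")
  rng <- range(raw)
  if (rng[1] == rng[2])
    stop("all raw scores are equal; 0-100 transform is degenerate")
  # divide before scaling so the extremes are exactly 0 and 100 in floating
  # point ((max - min) / (max - min) is exactly 1)
  ((raw - rng[1]) / (rng[2] - rng[1])) * 100
}

#' Combination score: prediction minus a weighted IPI
#'
#' `combined = normalized - weight * ipi`. At the default weight of 25 the
#' IPI term spans 125 over IPI 0..5, comparable to the 0-100 prediction
#' scale, so the two components get roughly equal weight.
#'
#' @param normalized 0-100 prediction scores.
#' @param ipi integer International Prognostic Index values in 0..5.
#' @param weight IPI weight (default 25).
#' @return combined scores (range -125..100 at the default weight).
#' @export
combination_score <- function(normalized, ipi, weight = 25) {
  if (length(normalized) != length(ipi))
    stop("normalized and ipi must have the same length")
  if (any(is.na(ipi)) || any(ipi != as.integer(ipi)) || any(ipi < 0 | ipi > 5))
    stop("ipi must be an integer in 0..5")
  normalized - weight * ipi
}

#' GCB/ABC subtype score
#'
#' Mean expression of the GCB-subtype features minus mean expression of the
#' ABC-subtype features, per sample. Features absent from the matrix are
#' dropped from their list's mean with a warning; at least one feature of
#' each list must be present.
#'
#' @param expr features x samples matrix (or named single-sample vector).
#' @param profile a [subtype_profile()].
#' @return named numeric vector of subtype scores.
#' @export
gcb_abc_score <- function(expr, profile) {
  stopifnot(inherits(profile, "subtype_profile"))
  if (!is.matrix(expr)) {
    if (is.null(names(expr))) stop("single-sample expression must be named")
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "sample"))
  }
  side_mean <- function(feats, label) {
    present <- intersect(feats, rownames(expr))
    if (!length(present))
      stop("no ", label, " subtype feature present in the expression matrix")
    if (length(present) < length(feats))
      warning(length(feats) - length(present), " ", label, " feature(s) ",
              "absent; mean taken over the remaining ", length(present))
    colMeans(expr[present, , drop = FALSE], na.rm = TRUE)
  }
  side_mean(profile$gcb_features, "GCB") - side_mean(profile$abc_features, "ABC")
}

#' Classify scores as sensitive or resistant
#'
#' Sensitive if and only if the score is greater than or equal to the
#' cutoff; a score exactly at the cutoff is called sensitive (documented
#' boundary convention).
#'
#' @param score numeric scores.
#' @param cutoff classification cutoff (default 50 on the 0-100 scale).
#' @return character vector of `"sensitive"` / `"resistant"`.
#' @export
classify <- function(score, cutoff = 50) {
  ifelse(score >= cutoff, "sensitive", "resistant")
}

#' Score a patient cohort against a signature
#'
#' Aligns the expression matrix with the clinical table, computes raw
#' prediction scores, rescales them to 0-100, and forms the combination
#' score with the IPI. By default the 0-100 normalization population is the
#' patient's treatment arm (each arm is rescaled separately, mirroring
#' per-profile normalization of treatment-matched patients); use
#' `norm_population = "cohort"` to rescale over all aligned patients at
#' once.
#'
#' @param expr features x samples log2 expression matrix.
#' @param signature a [response_signature()].
#' @param clinical `patient_records` data.frame.
#' @param ipi_weight IPI weight in the combination score (default 25).
#' @param cutoff sensitive/resistant cutoff on the normalized score
#'   (default 50).
#' @param norm_population `"arm"` (default) or `"cohort"`.
#' @return a [score_set()] in cohort order.
#' @export
score_cohort <- function(expr, signature, clinical, ipi_weight = 25,
                         cutoff = 50, norm_population = c("arm", "cohort")) {
  norm_population <- match.arg(norm_population)
  aligned <- align_cohort(expr, clinical)
  raw <- raw_prediction_score(aligned$expr, signature)
  if (norm_population == "cohort") {
    normalized <- normalize_scores(raw)
  } else {
    normalized <- rep(NA_real_, length(raw))
    for (arm in unique(aligned$clinical$treatment)) {
      idx <- aligned$clinical$treatment == arm
      normalized[idx] <- normalize_scores(raw[idx])
    }
  }
  combined <- combination_score(normalized, aligned$clinical$ipi,
                                weight = ipi_weight)
  score_set(aligned$clinical$patient_id, raw, normalized, combined,
            cutoff = cutoff)
}

#' Quantile-normalize raw intensities and take log2
#'
#' Utility for raw (unnormalized) positive intensity matrices: maps every
#' column onto the common quantile distribution, then applies log2. This is
#' a generic quantile stand-in for array preprocessing, not RMA; properly
#' background-corrected, normalized input is the package's expected
#' contract.
#'
#' @param raw positive intensity matrix, features x samples.
#' @return log2 matrix whose columns share an identical empirical
#'   distribution; within-column rank order is preserved.
#' @export
quantile_normalize_log2 <- function(raw) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("raw intensities must be positive and finite")
  message("quantile normalization stand-in applied (not RMA)")
  qn <- limma::normalizeQuantiles(raw, ties = TRUE)
  out <- log2(qn)
  dimnames(out) <- dimnames(raw)
  out
}
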