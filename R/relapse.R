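# Relapse treatment selection: score relapse patients against the
# signatures of the second/third-line regimens they received, split them at
# an optimized cutoff, compare survival between predicted-sensitive and
# predicted-resistant groups, and rank alternative regimens.

#' Assemble a panel of regimen signatures
#'
#' @param ... named [response_signature()] objects, or a single named list
#'   of them. Names are the regimen labels (e.g. COPE, DHAP, CVP, HDMTX,
#'   MVBCNS, ICE, bendamustine) and must be unique.
#' @return named list classed `regimen_panel`.
#' @export
regimen_panel <- function(...) {
  sigs <- list(...)
  if (length(sigs) == 1 && is.list(sigs[[1]]) &&
      !inherits(sigs[[1]], "response_signature"))
    sigs <- sigs[[1]]
  if (!length(sigs)) stop("regimen panel must contain at least one signature")
  if (is.null(names(sigs)) || any(!nzchar(names(sigs))))
    stop("every regimen signature must be named")
  if (anyDuplicated(names(sigs)))
    stop("duplicate regimen label(s): ",
         paste(unique(names(sigs)[duplicated(names(sigs))]), collapse = ", "))
  ok <- vapply(sigs, inherits, TRUE, "response_signature")
  if (!all(ok))
    stop("not a response_signature: ", paste(names(sigs)[!ok], collapse = ", "))
  structure(sigs, class = "regimen_panel")
}

#' Per-regimen normalized score matrix over a cohort
#'
#' Scores every regimen signature on every sample and rescales each
#' regimen's raw scores to 0-100 across the supplied cohort (the
#' normalization context for relapse analyses is the relapse cohort itself).
#'
#' @param expr features x patients log2 expression matrix.
#' @param panel a [regimen_panel()].
#' @return numeric matrix, regimens x patients, on the 0-100 scale.
#' @export
regimen_score_matrix <- function(expr, panel) {
  stopifnot(inherits(panel, "regimen_panel"))
  out <- t(vapply(panel, function(sig)
    normalize_scores(raw_prediction_score(expr, sig)),
    numeric(ncol(expr))))
  dimnames(out) <- list(names(panel), colnames(expr))
  out
}

#' Relapse prediction scores: average over the regimens received
#'
#' A relapse patient's score is the mean of the normalized (0-100) scores of
#' the second/third-line regimens they actually received, normalized across
#' the supplied relapse cohort.
#'
#' @param expr features x patients matrix for the relapse cohort (the
#'   normalization context).
#' @param regimens_by_patient named list (patient id -> character vector of
#'   regimen labels received); every patient must appear in `expr`.
#' @param panel a [regimen_panel()] covering every received regimen.
#' @return named numeric vector of relapse scores, one per listed patient.
#' @export
relapse_scores <- function(expr, regimens_by_patient, panel) {
  stopifnot(inherits(panel, "regimen_panel"))
  if (is.null(names(regimens_by_patient)))
    stop("regimens_by_patient must be named by patient id")
  missing_pat <- setdiff(names(regimens_by_patient), colnames(expr))
  if (length(missing_pat))
    stop("patient(s) absent from expression matrix: ",
         paste(missing_pat, collapse = ", "))
  received <- unique(unlist(regimens_by_patient))
  unknown <- setdiff(received, names(panel))
  if (length(unknown))
    stop("regimen(s) without a signature in the panel: ",
         paste(unknown, collapse = ", "))
  if (any(lengths(regimens_by_patient) == 0))
    stop("every patient must have received at least one regimen")
  mat <- regimen_score_matrix(expr, panel)
  vapply(names(regimens_by_patient), function(p)
    mean(mat[regimens_by_patient[[p]], p]), numeric(1))
}

#' Optimize the sensitive/resistant cutoff for relapse scores
#'
#' `mode = "logrank"` (default) searches the midpoints of consecutive sorted
#' unique scores and returns the cutoff maximizing the two-group log-rank
#' chi-square, subject to both groups containing at least `min_group`
#' patients; ties are broken toward the candidate nearest the median score.
#' `mode = "fixed_n"` instead returns the cutoff that labels exactly
#' `n_sensitive` patients sensitive.
#'
#' A cutoff chosen this way is data-optimized: log-rank p-values computed at
#' it are descriptive, not valid hypothesis tests. The returned object
#' carries `data_optimized = TRUE` to make that caveat machine-readable.
#'
#' @param scores relapse prediction scores.
#' @param times,events post-relapse survival data (same order).
#' @param min_group minimum group size (default 3).
#' @param mode `"logrank"` or `"fixed_n"`.
#' @param n_sensitive required for `mode = "fixed_n"`.
#' @return list of class `relapse_cutoff` with `cutoff`, `mode`,
#'   `data_optimized`, `note`, and (logrank mode) `chisq`.
#' @export
optimize_cutoff <- function(scores, times, events, min_group = 3,
                            mode = c("logrank", "fixed_n"),
                            n_sensitive = NULL) {
  mode <- match.arg(mode)
  n <- length(scores)
  if (n < 2 * min_group)
    stop("need at least 2 * min_group = ", 2 * min_group, " patients")
  if (mode == "fixed_n") {
    if (is.null(n_sensitive) || n_sensitive < 1 || n_sensitive >= n)
      stop("n_sensitive must be in 1..(n-1) for fixed_n mode")
    s <- sort(scores, decreasing = TRUE)
    cutoff <- (s[n_sensitive] + s[n_sensitive + 1]) / 2
    return(structure(list(cutoff = cutoff, mode = mode,
                          data_optimized = TRUE,
                          note = .CUTOFF_NOTE), class = "relapse_cutoff"))
  }
  u <- sort(unique(scores))
  if (length(u) < 2) stop("scores are constant; no cutoff separates groups")
  cands <- (u[-1] + u[-length(u)]) / 2
  ok <- vapply(cands, function(cc)
    sum(scores >= cc) >= min_group && sum(scores < cc) >= min_group, TRUE)
  if (!any(ok))
    stop("no cutoff leaves at least ", min_group, " patients in each group")
  cands <- cands[ok]
  chisq <- vapply(cands, function(cc)
    logrank_test(times, events, scores >= cc)$chisq, numeric(1))
  best <- chisq >= max(chisq) - 1e-12
  tied <- cands[best]
  cutoff <- tied[order(abs(tied - stats::median(scores)), tied)][1]
  structure(list(cutoff = cutoff, mode = mode,
                 chisq = max(chisq), data_optimized = TRUE,
                 note = .CUTOFF_NOTE), class = "relapse_cutoff")
}

.CUTOFF_NOTE <- paste("cutoff was data-optimized;",
                      "p-values at this cutoff are descriptive")

#' Compare survival between predicted-sensitive and predicted-resistant
#'
#' Splits the relapse cohort at the cutoff (score >= cutoff is sensitive),
#' fits Kaplan-Meier curves per group, and reports medians with confidence
#' intervals plus a log-rank comparison. If the cutoff came from
#' [optimize_cutoff()] the result is flagged as data-optimized.
#'
#' @param scores relapse prediction scores.
#' @param cutoff numeric cutoff or a `relapse_cutoff` object.
#' @param times,events post-relapse survival data.
#' @param ci_level confidence level for median CIs (default 0.90).
#' @return list with `medians` (data.frame per group), `curves` (named list
#'   of [survival::survfit] objects), `logrank`, `data_optimized`, `note`.
#' @export
compare_relapse_survival <- function(scores, cutoff, times, events,
                                     ci_level = 0.90) {
  optimized <- inherits(cutoff, "relapse_cutoff")
  cut_val <- if (optimized) cutoff$cutoff else cutoff
  calls <- classify(scores, cut_val)
  if (length(unique(calls)) < 2)
    stop("all patients fall in one predicted group at cutoff ", cut_val)
  groups <- c("sensitive", "resistant")
  med <- do.call(rbind, lapply(groups, function(g) {
    idx <- calls == g
    m <- median_survival(times[idx], events[idx], ci_level = ci_level)
    data.frame(group = g, n = sum(idx), median = m$median,
               ci_lower = m$ci_lower, ci_upper = m$ci_upper,
               reached = m$reached, stringsAsFactors = FALSE)
  }))
  curves <- lapply(stats::setNames(groups, groups), function(g)
    km_curve(times[calls == g], events[calls == g], ci_level = ci_level))
  list(medians = med, curves = curves,
       logrank = logrank_test(times, events, calls),
       cutoff = cut_val, data_optimized = optimized,
       note = if (optimized) .CUTOFF_NOTE else NULL)
}

#' Rank all panel regimens for each patient
#'
#' Scores every regimen in the panel on every patient (normalized 0-100
#' across the supplied cohort), sorts regimens per patient by descending
#' score with alphabetical tie-breaking, and calls each regimen sensitive or
#' resistant at the cutoff.
#'
#' @param expr features x patients matrix (the normalization context).
#' @param panel a [regimen_panel()].
#' @param cutoff sensitive/resistant cutoff (default 50).
#' @return data.frame with `patient_id`, `rank`, `regimen`,
#'   `normalized_score`, `call`.
#' @export
recommend_regimens <- function(expr, panel, cutoff = 50) {
  mat <- regimen_score_matrix(expr, panel)
  out <- do.call(rbind, lapply(colnames(mat), function(p) {
    sc <- mat[, p]
    ord <- order(-sc, names(sc))
    data.frame(patient_id = p, rank = seq_along(ord),
               regimen = names(sc)[ord],
               normalized_score = unname(sc[ord]),
               call = classify(sc[ord], cutoff),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Concordance between primary and relapse biopsy predictions
#'
#' Pairs scores by patient, reports their Pearson correlation and how many
#' pairs lie above, below, and on the identity diagonal (relapse vs primary).
#' With fewer than 3 pairs the correlation is undefined and reported `NA`.
#'
#' @param primary_scores,relapse_scores named numeric vectors; pairing uses
#'   the shared names (or positions if unnamed and equal length).
#' @return list with `r`, `n`, `n_above`, `n_below`, `n_on_diagonal`.
#' @export
biopsy_concordance <- function(primary_scores, relapse_scores) {
  if (!is.null(names(primary_scores)) && !is.null(names(relapse_scores))) {
    common <- intersect(names(primary_scores), names(relapse_scores))
    if (!length(common)) stop("no shared patient ids between score vectors")
    primary_scores <- primary_scores[common]
    relapse_scores <- relapse_scores[common]
  } else if (length(primary_scores) != length(relapse_scores)) {
    stop("unnamed score vectors must have equal length")
  }
  n <- length(primary_scores)
  r <- if (n >= 3) {
    v <- suppressWarnings(stats::cor(primary_scores, relapse_scores))
    if (is.na(v)) NA_real_ else v
  } else NA_real_
  list(r = r, n = n,
       n_above = sum(relapse_scores > primary_scores),
       n_below = sum(relapse_scores < primary_scores),
       n_on_diagonal = sum(relapse_scores == primary_scores))
}
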