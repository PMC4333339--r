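# Validation statistics: ordinal response coding, one-sided Wilcoxon,
# score-response correlation, Kaplan-Meier / log-rank survival analysis,
# ROC/AUC, the multivariate logistic remission model, and the endpoint x
# method summary table.

#' Ordinal response coding and responder definition
#'
#' Clinical responses are coded CR = 5, CRu = 4, PR = 3, SD = 2, PD = 1,
#' Dead (before response evaluation) = 0; Unevaluable records are always
#' excluded. Responders are CR + CRu by default; `"cr_only"` treats CR alone
#' as response (every other evaluable category is a non-response).
#' `include_dead = FALSE` additionally drops the dead-before-evaluation
#' category (a sensitivity analysis: deaths from toxicity are not disease
#' progression).
#'
#' @param responder_def `"cr_cru"` (default) or `"cr_only"`.
#' @param include_dead keep the Dead category in response analyses
#'   (default TRUE).
#' @return object of class `response_coding`.
#' @export
response_coding <- function(responder_def = c("cr_cru", "cr_only"),
                            include_dead = TRUE) {
  structure(list(map = c(CR = 5, CRu = 4, PR = 3, SD = 2, PD = 1, Dead = 0),
                 responder_def = match.arg(responder_def),
                 include_dead = isTRUE(include_dead)),
            class = "response_coding")
}

#' Encode responses on the ordinal scale
#' @param responses character vector of [RESPONSE_CATEGORIES] labels.
#' @param coding a [response_coding()].
#' @return numeric codes; `NA` for excluded records (Unevaluable, and Dead
#'   when `include_dead = FALSE`).
#' @export
encode_response <- function(responses, coding = response_coding()) {
  stopifnot(inherits(coding, "response_coding"))
  idx <- match(toupper(as.character(responses)), toupper(RESPONSE_CATEGORIES))
  if (any(is.na(idx)))
    stop("unknown response label(s): ",
         paste(unique(responses[is.na(idx)]), collapse = ", "))
  canon <- RESPONSE_CATEGORIES[idx]
  code <- unname(coding$map[canon])
  code[canon == "Unevaluable"] <- NA_real_
  if (!coding$include_dead) code[canon == "Dead"] <- NA_real_
  code
}

#' Responder status under a coding
#' @inheritParams encode_response
#' @return logical vector; `NA` for excluded records.
#' @export
responder_status <- function(responses, coding = response_coding()) {
  code <- encode_response(responses, coding)
  resp_codes <- if (coding$responder_def == "cr_cru") c(5, 4) else 5
  ifelse(is.na(code), NA, code %in% resp_codes)
}

#' One-sided Wilcoxon rank-sum test (responders hypothesized higher)
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. Two groups with no score variation at all give p = 1 (no
#' evidence either way).
#'
#' @param scores_responders,scores_nonresponders numeric vectors, both
#'   non-empty.
#' @return one-sided p-value for the alternative "responders higher".
#' @export
wilcoxon_one_sided <- function(scores_responders, scores_nonresponders) {
  x <- scores_responders
  y <- scores_nonresponders
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1) return(1)
  use_exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = use_exact,
                       correct = TRUE)$p.value
  )
}

#' Correlation between prediction score and ordinal clinical response
#'
#' Pearson correlation between scores and the ordinal response codes
#' (Unevaluable excluded), with a one-sided p-value for the positive
#' direction from the t distribution with n - 2 degrees of freedom.
#'
#' @param scores numeric prediction scores.
#' @param responses response labels, same length.
#' @param coding a [response_coding()].
#' @return list with `cc`, `p`, `n`.
#' @export
response_correlation <- function(scores, responses,
                                 coding = response_coding()) {
  if (length(scores) != length(responses))
    stop("scores and responses must have the same length")
  code <- encode_response(responses, coding)
  keep <- !is.na(code) & !is.na(scores)
  n <- sum(keep)
  if (n < 3) stop("fewer than 3 evaluable patients")
  cc <- stats::cor(scores[keep], code[keep])
  if (is.na(cc)) stop("correlation undefined (zero variance)")
  p <- if (cc >= 1) 0 else if (cc <= -1) 1 else
    stats::pt(cc * sqrt((n - 2) / (1 - cc^2)), df = n - 2, lower.tail = FALSE)
  list(cc = cc, p = p, n = n)
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate with log-log ("log(-log)") confidence intervals.
#'
#' @param times non-negative survival times.
#' @param events event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @param ci_level confidence level (default 0.90).
#' @return a [survival::survfit] object.
#' @export
km_curve <- function(times, events, ci_level = 0.90) {
  stopifnot(all(times >= 0))
  survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                    conf.type = "log-log", conf.int = ci_level)
}

#' Median survival with confidence interval
#'
#' Median = earliest time at which the Kaplan-Meier estimate drops to 0.5 or
#' below; the CI uses the log-log construction at the configured level. When
#' the curve never reaches 0.5 the median is not reached (`NA`).
#'
#' @inheritParams km_curve
#' @return list with `median`, `ci_lower`, `ci_upper`, `reached`.
#' @export
median_survival <- function(times, events, ci_level = 0.90) {
  fit <- km_curve(times, events, ci_level = ci_level)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  lcl <- unname(tab[grep("LCL$", names(tab))])
  ucl <- unname(tab[grep("UCL$", names(tab))])
  list(median = med, ci_lower = lcl, ci_upper = ucl, reached = !is.na(med))
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square with k - 1 degrees of freedom (1 df for two
#' groups). With no events at all in any group the statistic is 0, p = 1.
#'
#' @param times non-negative survival times.
#' @param events event indicators.
#' @param group group labels (at least 2 groups, each non-empty).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 1)) stop("every group needs at least 1 subject")
  if (sum(as.integer(events)) == 0)
    return(list(chisq = 0, df = nlevels(group) - 1, p = 1))
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' ROC curve and AUC of a score against responder labels
#'
#' Curve over all distinct score thresholds; the trapezoidal AUC equals the
#' Mann-Whitney concordance probability with half credit for ties.
#'
#' @param scores numeric scores (higher = more likely responder).
#' @param labels logical (or 0/1) responder labels; both classes must be
#'   present.
#' @return list with `curve` (data.frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both responder and non-responder labels must be present")
  r <- pROC::roc(response = factor(labels, levels = c(FALSE, TRUE)),
                 predictor = scores, direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  rownames(curve) <- NULL
  list(curve = curve, auc = as.numeric(r$auc))
}

#' Multivariate logistic remission model
#'
#' Fits `remission ~ A * prediction + B * ipi (+ C * gcb_abc)` by
#' maximum-likelihood logistic regression and reports one-sided Wald
#' p-values for the hypothesized directions: higher prediction helps
#' (A > 0), higher IPI hurts (B < 0), more GCB-like helps (C > 0).
#' Covariates without variation are reported inestimable. Under complete
#' separation the fit is flagged and refit with a small ridge penalty.
#'
#' @param prediction normalized 0-100 prediction scores.
#' @param ipi IPI values 0..5.
#' @param gcb_abc optional GCB/ABC subtype scores.
#' @param remission logical remission (responder) labels.
#' @param ridge penalty used by the separation fallback (default 1e-2).
#' @return list with `coefficients`, `se`, `z`, `p_one_sided` (all named),
#'   `converged`, `separation`, `inestimable`, `method`.
#' @export
multivariate_remission_fit <- function(prediction, ipi, gcb_abc = NULL,
                                       remission, ridge = 1e-2) {
  y <- as.logical(remission)
  covs <- list(prediction = prediction, ipi = ipi)
  if (!is.null(gcb_abc)) covs$gcb_abc <- gcb_abc
  n <- length(y)
  if (any(vapply(covs, length, 1L) != n))
    stop("covariates and remission labels must have the same length")
  if (anyNA(y) || any(vapply(covs, anyNA, TRUE)))
    stop("missing values in covariates or remission labels")
  signs <- c(prediction = 1, ipi = -1, gcb_abc = 1)[names(covs)]
  inest <- vapply(covs, function(v) length(unique(v)) < 2, TRUE)
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, covs[!inest]))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  if (sep || !fit$converged || any(abs(beta[-1]) > 15)) {
    sep <- TRUE
    warning("separation or non-convergence detected; ",
            "refitting with a small ridge penalty")
    rf <- .ridge_logistic(X, y, lambda = ridge)
    beta <- rf$beta
    se <- rf$se
    method <- "ridge"
  } else {
    W <- fit$weights
    info <- crossprod(X * sqrt(W))
    se <- sqrt(diag(solve(info)))
    method <- "ml"
  }
  full <- setdiff(names(covs), "")
  coefs <- stats::setNames(rep(NA_real_, length(full)), full)
  ses <- zs <- ps <- coefs
  est_names <- intersect(full, names(beta))
  coefs[est_names] <- beta[est_names]
  ses[est_names] <- se[match(est_names, colnames(X))]
  zs[est_names] <- coefs[est_names] / ses[est_names]
  for (nm in est_names) {
    ps[nm] <- if (signs[nm] > 0)
      stats::pnorm(zs[nm], lower.tail = FALSE)
    else stats::pnorm(zs[nm])
  }
  list(coefficients = coefs, se = ses, z = zs, p_one_sided = ps,
       intercept = unname(beta["(Intercept)"]),
       converged = if (method == "ml") fit$converged else TRUE,
       separation = sep, inestimable = names(covs)[inest], method = method)
}

#' Endpoint-by-method summary table of validation p-values
#'
#' Rows Remission / Overall survival / Progression-free survival, columns
#' Prediction / IPI / Combined / GCB_ABC. The remission row holds one-sided
#' Wilcoxon p-values comparing responders with non-responders on each score
#' (the IPI enters with its natural order reversed, since low IPI is
#' favorable); the survival rows hold log-rank p-values at each method's
#' cutoff: prediction at 50 on the 0-100 scale, IPI at the standard
#' high-risk split >= 3, the combined score at its cohort median by default,
#' and the GCB/ABC score at 0. Cells whose split leaves an empty group are
#' `NA` with a warning.
#'
#' @param scores a [score_set()].
#' @param clinical `patient_records` aligned with the scores.
#' @param gcb_abc optional per-patient GCB/ABC scores (same order).
#' @param coding a [response_coding()].
#' @param prediction_cutoff,ipi_cutoff,combined_cutoff,gcb_cutoff log-rank
#'   dichotomization cutoffs; `combined_cutoff = NULL` uses the cohort
#'   median.
#' @return 3 x 4 numeric matrix of p-values.
#' @export
summary_table <- function(scores, clinical, gcb_abc = NULL,
                          coding = response_coding(),
                          prediction_cutoff = 50, ipi_cutoff = 3,
                          combined_cutoff = NULL, gcb_cutoff = 0) {
  df <- merge(as.data.frame(scores), as.data.frame(clinical),
              by = "patient_id", sort = FALSE)
  if (!nrow(df)) stop("scores and clinical table share no patients")
  if (!is.null(gcb_abc)) {
    if (length(gcb_abc) != nrow(as.data.frame(scores)))
      stop("gcb_abc must match the score set length")
    df$gcb <- gcb_abc[match(df$patient_id,
                            as.data.frame(scores)$patient_id)]
  }
  if (is.null(combined_cutoff)) combined_cutoff <- stats::median(df$combined)
  resp <- responder_status(df$response, coding)
  wil <- function(v) {
    keep <- !is.na(resp)
    if (!any(resp[keep]) || all(resp[keep])) return(NA_real_)
    wilcoxon_one_sided(v[keep][resp[keep]], v[keep][!resp[keep]])
  }
  lr <- function(times, events, split) {
    if (length(unique(split)) < 2) {
      warning("degenerate survival split; p set to NA")
      return(NA_real_)
    }
    logrank_test(times, events, split)$p
  }
  methods <- list(
    Prediction = list(score = df$normalized,
                      split = df$normalized >= prediction_cutoff),
    IPI = list(score = -df$ipi, split = df$ipi >= ipi_cutoff),
    Combined = list(score = df$combined,
                    split = df$combined >= combined_cutoff),
    GCB_ABC = if (is.null(gcb_abc)) NULL else
      list(score = df$gcb, split = df$gcb >= gcb_cutoff)
  )
  out <- matrix(NA_real_, nrow = 3, ncol = 4,
                dimnames = list(c("Remission", "Overall survival",
                                  "Progression-free survival"),
                                names(methods)))
  for (m in names(methods)) {
    if (is.null(methods[[m]])) next
    out["Remission", m] <- wil(methods[[m]]$score)
    out["Overall survival", m] <-
      lr(df$os_days, df$os_event, methods[[m]]$split)
    out["Progression-free survival", m] <-
      lr(df$pfs_days, df$pfs_event, methods[[m]]$split)
  }
  out
}

# ---- internal ---------------------------------------------------------

# Ridge-penalized logistic regression by IRLS; intercept unpenalized.
# Used only as the separation fallback of multivariate_remission_fit().
.ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100,
                            tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * sqrt(W)) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se = se)
}
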