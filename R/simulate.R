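# Synthetic data generators. All generators are pure functions of their
# parameter objects (which include the seed): the same parameters always
# reproduce the same data bit-for-bit.
#
# The cell-line panel model: each cell line c has a latent chemosensitivity
# s_c ~ N(0, 1). Per-drug -log10(GI50) = beta_drug * s_c + assay noise;
# planted ("informative") expression features = baseline + gamma * s_c +
# measurement noise on the log2 scale; all other features are pure noise.
#
# The patient cohort model: each patient p has a latent sensitivity s_p
# driving the same planted features, and an ordinal response latent
# u = a1 * s_p - a2 * IPI + noise thresholded into the clinical response
# categories. Survival is exponential with hazard increasing in
# non-response and IPI, under independent uniform censoring. Relapse
# patients receive second/third-line regimens whose planted per-regimen
# sensitivities drive both regimen-specific expression features and
# post-relapse survival.

#' Parameters for the synthetic cell-line panel
#'
#' Defaults emulate a 60-cell-line screening panel profiled for 1756
#' microRNA features, with 20 informative features and a drug-loading
#' pattern in which vincristine and doxorubicin carry most of the
#' combination's signal while cyclophosphamide (a prodrug with a narrow
#' in-vitro GI50 range) contributes little.
#'
#' @param n_cell_lines number of cell lines (default 60).
#' @param n_features number of expression features (default 1756).
#' @param n_informative number of planted informative features (default 20).
#' @param drug_loadings named per-drug loadings on the latent sensitivity.
#' @param feature_loading loading gamma of planted features on the latent
#'   sensitivity (default 0.8, log2 units per latent SD).
#' @param expr_noise_sd log2 expression measurement noise SD (default 1.0).
#' @param gi50_noise_sd per-drug -log10(GI50) assay noise SD (default 0.6).
#' @param baseline_log2 baseline log2 expression level (default 7).
#' @param seed RNG seed (default 20150218).
#' @return list of class `panel_sim_params`.
#' @export
panel_sim_params <- function(n_cell_lines = 60, n_features = 1756,
                             n_informative = 20,
                             drug_loadings = c(vincristine = 0.6,
                                               doxorubicin = 0.6,
                                               cyclophosphamide = 0.1),
                             feature_loading = 0.8, expr_noise_sd = 1.0,
                             gi50_noise_sd = 0.6, baseline_log2 = 7,
                             seed = 20150218) {
  stopifnot(n_informative <= n_features, n_cell_lines >= 3,
            all(is.finite(drug_loadings)), !is.null(names(drug_loadings)),
            is.finite(feature_loading), expr_noise_sd >= 0,
            gi50_noise_sd >= 0)
  structure(as.list(environment()), class = "panel_sim_params")
}

#' Simulate a cell-line drug-sensitivity panel with planted signal
#'
#' @param params a [panel_sim_params()].
#' @return list with `panel` (drugs x cell lines -log10(GI50)), `expr`
#'   (features x cell lines log2 expression), and `truth` (planted feature
#'   ids and the latent sensitivity vector).
#' @export
simulate_cell_line_panel <- function(params = panel_sim_params()) {
  stopifnot(inherits(params, "panel_sim_params"))
  set.seed(params$seed)
  n <- params$n_cell_lines
  cells <- sprintf("CL%02d", seq_len(n))
  s <- stats::rnorm(n)
  drugs <- names(params$drug_loadings)
  panel <- outer(params$drug_loadings, s) +
    matrix(stats::rnorm(length(drugs) * n, sd = params$gi50_noise_sd),
           nrow = length(drugs))
  dimnames(panel) <- list(drugs, cells)
  feats <- .sim_feature_ids(params$n_features)
  planted <- sort(sample(feats, params$n_informative))
  expr <- matrix(stats::rnorm(params$n_features * n,
                              mean = params$baseline_log2,
                              sd = params$expr_noise_sd),
                 nrow = params$n_features, dimnames = list(feats, cells))
  expr[planted, ] <- expr[planted, , drop = FALSE] +
    params$feature_loading * matrix(s, length(planted), n, byrow = TRUE)
  list(panel = drug_response_panel(panel),
       expr = expression_matrix(expr),
       truth = list(planted_features = planted, latent_sensitivity =
                      stats::setNames(s, cells)))
}

# Response-category thresholds on the ordinal latent u = a1*s - a2*IPI + e.
# Quantile-calibrated once against the validation cohort's category
# frequencies (Dead 5, PD 2, SD 0, PR 5, CRu 42, CR 57 of 111 evaluable)
# at the default effect sizes (a1 = 0.5, a2 = 0.4), then fixed. Ascending
# boundaries Dead | PD | SD | PR | CRu | CR; the SD interval has zero width
# because the cohort being emulated contained no stable-disease responses.
.RESPONSE_THRESHOLDS <- c(-2.980948, -2.775903, -2.775903, -2.412711,
                          -0.921320)
.RESPONSE_LEVELS <- c("Dead", "PD", "SD", "PR", "CRu", "CR")

#' Parameters for the synthetic patient cohort
#'
#' Defaults emulate a 116-patient first-line cohort: the observed IPI
#' distribution, treatment split, response-category frequencies (via
#' fixed quantile-calibrated thresholds), about 19% deaths under the
#' censoring horizon, 5 unevaluable patients, and roughly 13 relapses with
#' second/third-line regimens drawn from COPE, DHAP, CVP, HDMTX, MVBCNS.
#' Effect sizes default to `score_effect = 0.5` and `ipi_effect = 0.4`,
#' chosen once so the synthetic cohort's score-response correlation
#' (about 0.3) and the relative strength of score and IPI resemble the
#' clinical behavior the pipeline targets.
#'
#' @param n_patients cohort size (default 116).
#' @param ipi_probs IPI category probabilities for IPI 0..5.
#' @param score_effect,ipi_effect effects a1, a2 of latent sensitivity and
#'   IPI on the ordinal response latent.
#' @param n_features,n_informative,feature_loading,expr_noise_sd,baseline_log2
#'   expression model, as in [panel_sim_params()].
#' @param planted_features optional character vector of planted feature ids
#'   (e.g. from a simulated panel's truth) so patient expression aligns with
#'   a signature built on the panel; must be drawn from the same feature
#'   universe. `NULL` samples a fresh set.
#' @param treatment_probs named first-line treatment probabilities.
#' @param n_unevaluable number of patients marked response-unevaluable.
#' @param base_hazard baseline death hazard per day.
#' @param nonresponder_loghr,ipi_loghr log hazard ratios for non-response
#'   and per IPI point.
#' @param progression_base_hazard baseline progression hazard per day.
#' @param censor_range uniform censoring window in days.
#' @param relapse_fraction probability that a responding (CR/CRu/PR) patient
#'   relapses and receives second/third-line treatment.
#' @param regimen_labels second/third-line regimen labels.
#' @param n_regimen_features planted features per regimen signature.
#' @param regimen_match_loghr log hazard reduction per unit of
#'   regimen-match score on post-relapse survival.
#' @param relapse_base_hazard baseline post-relapse death hazard per day.
#' @param relapse_censor_range post-relapse censoring window in days.
#' @param seed RNG seed (default 20150218).
#' @return list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 116,
                              ipi_probs = c(10, 28, 37, 18, 16, 7) / 116,
                              score_effect = 0.5, ipi_effect = 0.4,
                              n_features = 1756, n_informative = 20,
                              feature_loading = 0.8, expr_noise_sd = 1.0,
                              baseline_log2 = 7, planted_features = NULL,
                              treatment_probs = c("R-CHOP" = 95 / 116,
                                                  "R-CHOEP" = 21 / 116),
                              n_unevaluable = 5, base_hazard = 1e-4,
                              nonresponder_loghr = 1.5, ipi_loghr = 0.25,
                              progression_base_hazard = 8e-5,
                              censor_range = c(400, 2500),
                              relapse_fraction = 0.12,
                              regimen_labels = c("COPE", "DHAP", "CVP",
                                                 "HDMTX", "MVBCNS"),
                              n_regimen_features = 10,
                              regimen_match_loghr = 0.8,
                              relapse_base_hazard = 1 / 600,
                              relapse_censor_range = c(200, 1400),
                              seed = 20150218) {
  stopifnot(abs(sum(ipi_probs) - 1) < 1e-8, length(ipi_probs) == 6,
            all(ipi_probs >= 0), base_hazard > 0,
            progression_base_hazard > 0, relapse_base_hazard > 0,
            n_informative <= n_features,
            n_unevaluable < n_patients, relapse_fraction >= 0,
            relapse_fraction <= 1)
  structure(as.list(environment()), class = "cohort_sim_params")
}

#' Simulate a patient cohort with planted score and IPI effects
#'
#' @param params a [cohort_sim_params()].
#' @return list with `expr` (features x patients), `clinical`
#'   (`patient_records` with extra `post_relapse_os_days` /
#'   `post_relapse_os_event` columns for relapse patients),
#'   `regimen_signatures` (a [regimen_panel()] of generator-derived
#'   signatures over the planted per-regimen features), and `truth` (latent
#'   sensitivities, per-regimen latent sensitivities, planted feature ids).
#' @export
simulate_patient_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  ids <- sprintf("PT%03d", seq_len(n))
  s <- stats::rnorm(n)
  ipi <- sample(0:5, n, replace = TRUE, prob = params$ipi_probs)
  treatment <- sample(names(params$treatment_probs), n, replace = TRUE,
                      prob = params$treatment_probs)

  # ordinal response
  u <- params$score_effect * s - params$ipi_effect * ipi + stats::rnorm(n)
  response <- .RESPONSE_LEVELS[findInterval(u, .RESPONSE_THRESHOLDS) + 1]
  responder <- response %in% c("CR", "CRu")

  # expression: planted features track s, the rest are noise
  feats <- .sim_feature_ids(params$n_features)
  if (is.null(params$planted_features)) {
    planted <- sort(sample(feats, params$n_informative))
  } else {
    planted <- params$planted_features
    if (!all(planted %in% feats))
      stop("planted_features must come from the generator's feature universe")
  }
  expr <- matrix(stats::rnorm(params$n_features * n,
                              mean = params$baseline_log2,
                              sd = params$expr_noise_sd),
                 nrow = params$n_features, dimnames = list(feats, ids))
  expr[planted, ] <- expr[planted, , drop = FALSE] +
    params$feature_loading * matrix(s, length(planted), n, byrow = TRUE)

  # per-regimen latent sensitivities + regimen-specific planted features
  regs <- params$regimen_labels
  s_reg <- matrix(stats::rnorm(n * length(regs)), nrow = n,
                  dimnames = list(ids, regs))
  pool <- setdiff(feats, planted)
  if (length(pool) < length(regs) * params$n_regimen_features)
    stop("not enough null features for the regimen signatures")
  reg_feats <- split(sample(pool, length(regs) * params$n_regimen_features),
                     rep(regs, each = params$n_regimen_features))
  for (r in regs) {
    expr[reg_feats[[r]], ] <- expr[reg_feats[[r]], , drop = FALSE] +
      params$feature_loading *
        matrix(s_reg[, r], params$n_regimen_features, n, byrow = TRUE)
  }
  # generator-derived signatures: the planted feature-latent correlation
  plant_r <- params$feature_loading /
    sqrt(params$feature_loading^2 + params$expr_noise_sd^2)
  regimen_signatures <- regimen_panel(lapply(
    stats::setNames(regs, regs), function(r)
      response_signature(r, data.frame(
        feature_id = sort(reg_feats[[r]]),
        selection_correlation = plant_r), threshold = 0.25)))

  # first-line survival
  dead_early <- response == "Dead"
  loghr <- params$ipi_loghr * ipi + params$nonresponder_loghr * !responder
  t_death <- stats::rexp(n, rate = params$base_hazard * exp(loghr))
  t_prog <- stats::rexp(n, rate = params$progression_base_hazard * exp(loghr))
  cens <- stats::runif(n, params$censor_range[1], params$censor_range[2])
  os_days <- pmin(t_death, cens)
  os_event <- t_death <= cens
  pfs_days <- pmin(t_prog, t_death, cens)
  pfs_event <- pmin(t_prog, t_death) <= cens
  # dead before response evaluation: early deaths, always observed
  os_days[dead_early] <- round(stats::runif(sum(dead_early), 20, 120))
  os_event[dead_early] <- TRUE
  pfs_days[dead_early] <- os_days[dead_early]
  pfs_event[dead_early] <- TRUE
  os_days <- round(os_days)
  pfs_days <- pmin(round(pfs_days), os_days)

  # relapse assignment and post-relapse survival
  can_relapse <- response %in% c("CR", "CRu", "PR")
  relapse <- can_relapse &
    stats::runif(n) < params$relapse_fraction
  regimens <- vector("list", n)
  post_days <- rep(NA_real_, n)
  post_event <- rep(NA, n)
  for (i in which(relapse)) {
    k <- sample(1:2, 1)
    regimens[[i]] <- sample(regs, k)
    match_score <- mean(s_reg[i, regimens[[i]]])
    rate <- params$relapse_base_hazard *
      exp(-params$regimen_match_loghr * match_score)
    t2 <- stats::rexp(1, rate)
    c2 <- stats::runif(1, params$relapse_censor_range[1],
                       params$relapse_censor_range[2])
    post_days[i] <- round(min(t2, c2))
    post_event[i] <- t2 <= c2
  }

  # mask a fixed number of patients as unevaluable (survival keeps the
  # underlying category's hazard; only the recorded response is masked)
  response[sample(n, params$n_unevaluable)] <- "Unevaluable"

  clinical <- patient_records(data.frame(
    patient_id = ids, ipi = ipi, treatment = treatment, response = response,
    os_days = os_days, os_event = os_event, pfs_days = pfs_days,
    pfs_event = pfs_event, relapse = relapse,
    relapse_regimens = vapply(regimens, paste, "", collapse = ";"),
    stringsAsFactors = FALSE))
  clinical$post_relapse_os_days <- post_days
  clinical$post_relapse_os_event <- post_event

  list(expr = expression_matrix(expr), clinical = clinical,
       regimen_signatures = regimen_signatures,
       truth = list(latent_sensitivity = stats::setNames(s, ids),
                    regimen_sensitivity = s_reg,
                    planted_features = planted,
                    regimen_features = reg_feats))
}

#' Parameters for matched primary/relapse biopsy pairs
#'
#' @param n_pairs number of patients with both biopsies (default 10).
#' @param n_features,n_informative,feature_loading,expr_noise_sd,baseline_log2
#'   expression model as in [panel_sim_params()].
#' @param drift_sd SD of the independent per-feature noise added to the
#'   primary biopsy to form the relapse biopsy (default 1.0; no systematic
#'   resistance drift).
#' @param seed RNG seed.
#' @return list of class `relapse_sim_params`.
#' @export
relapse_sim_params <- function(n_pairs = 10, n_features = 1756,
                               n_informative = 20, feature_loading = 0.8,
                               expr_noise_sd = 1.0, baseline_log2 = 7,
                               drift_sd = 1.0, seed = 20150218) {
  stopifnot(n_pairs >= 1, n_informative <= n_features, drift_sd >= 0)
  structure(as.list(environment()), class = "relapse_sim_params")
}

#' Simulate matched primary and relapse biopsy expression pairs
#'
#' Relapse expression equals the primary expression plus independent
#' per-feature noise (`drift_sd`), with no systematic resistance drift, so
#' paired prediction scores correlate positively and scatter symmetrically
#' about the identity diagonal.
#'
#' @param params a [relapse_sim_params()].
#' @return list with `primary_expr`, `relapse_expr` (features x patients)
#'   and `truth` (planted feature ids, latent sensitivities).
#' @export
simulate_relapse_cohort <- function(params = relapse_sim_params()) {
  stopifnot(inherits(params, "relapse_sim_params"))
  set.seed(params$seed)
  n <- params$n_pairs
  ids <- sprintf("PT%03d", seq_len(n))
  s <- stats::rnorm(n)
  feats <- .sim_feature_ids(params$n_features)
  planted <- sort(sample(feats, params$n_informative))
  primary <- matrix(stats::rnorm(params$n_features * n,
                                 mean = params$baseline_log2,
                                 sd = params$expr_noise_sd),
                    nrow = params$n_features, dimnames = list(feats, ids))
  primary[planted, ] <- primary[planted, , drop = FALSE] +
    params$feature_loading * matrix(s, length(planted), n, byrow = TRUE)
  drift <- matrix(stats::rnorm(params$n_features * n, sd = params$drift_sd),
                  nrow = params$n_features)
  relapse <- primary + drift
  list(primary_expr = expression_matrix(primary),
       relapse_expr = expression_matrix(relapse),
       truth = list(planted_features = planted,
                    latent_sensitivity = stats::setNames(s, ids)))
}

.sim_feature_ids <- function(n_features) {
  sprintf("hsa-miR-sim-%04d_st", seq_len(n_features))
}
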