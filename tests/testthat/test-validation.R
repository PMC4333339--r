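test_that("one-sided Wilcoxon matches exact enumeration on the toy split", {
  # oracle: enumerate all C(6,3) assignments of ranks to the responder group
  pool <- c(1, 2, 3, 4, 5, 6)
  obs <- sum(rank(pool)[4:6])
  splits <- combn(6, 3)
  exact <- mean(apply(splits, 2, function(ix) sum(rank(pool)[ix]) >= obs))
  expect_equal(exact, 1 / 20)
  expect_equal(wilcoxon_one_sided(c(4, 5, 6), c(1, 2, 3)), exact)
  expect_equal(wilcoxon_one_sided(1, 1), 1)           # no evidence under ties
  expect_gt(wilcoxon_one_sided(c(1, 2, 3), c(4, 5, 6)), 0.5)  # wrong direction
  expect_error(wilcoxon_one_sided(numeric(0), 1), "non-empty")
})

test_that("response coding follows the ordinal category order", {
  coding <- response_coding()
  codes <- encode_response(c("CR", "CRu", "PR", "SD", "PD", "Dead",
                             "Unevaluable"), coding)
  expect_equal(codes, c(5, 4, 3, 2, 1, 0, NA))
  expect_equal(responder_status(c("CR", "CRu", "PR", "Dead"), coding),
               c(TRUE, TRUE, FALSE, FALSE))
  cr_only <- response_coding("cr_only")
  expect_equal(responder_status(c("CR", "CRu"), cr_only), c(TRUE, FALSE))
  no_dead <- response_coding(include_dead = FALSE)
  expect_true(is.na(encode_response("Dead", no_dead)))
})

test_that("score-response correlation matches the formula oracle", {
  resp <- c("CR", "CRu", "PR", "PD", "Dead")
  codes <- c(5, 4, 3, 1, 0)
  perfect <- response_correlation(codes, resp)
  expect_equal(perfect$cc, 1)
  expect_equal(perfect$p, 0)
  scores <- c(61, 40, 55, 20, 33)
  got <- response_correlation(scores, resp)
  r <- pearson_oracle(scores, codes)
  expect_equal(got$cc, r, tolerance = 1e-12)
  tstat <- r * sqrt(3 / (1 - r^2))
  expect_equal(got$p, pt(tstat, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # unevaluable records are excluded from the correlation
  with_ue <- response_correlation(c(scores, 99), c(resp, "Unevaluable"))
  expect_equal(with_ue$n, 5)
  expect_equal(with_ue$cc, got$cc)
})

test_that("Kaplan-Meier estimates match the hand-computed product-limit table", {
  # 6 subjects: times 6,7,10,15,19,25; events 1,0,1,1,0,1
  # S: 5/6 (t=6), 5/6*3/4 = 0.625 (t=10), 0.625*2/3 = 5/12 (t=15), 0 (t=25)
  fit <- km_curve(c(6, 7, 10, 15, 19, 25), c(1, 0, 1, 1, 0, 1))
  s <- summary(fit)
  expect_equal(s$time, c(6, 10, 15, 25))
  expect_equal(s$surv, c(5 / 6, 5 / 8, 5 / 12, 0), tolerance = 1e-12)
  med <- median_survival(c(6, 7, 10, 15, 19, 25), c(1, 0, 1, 1, 0, 1))
  expect_equal(med$median, 15)   # earliest time with S <= 0.5
  expect_true(med$reached)

  expect_equal(median_survival(c(100, 200, 300), c(1, 1, 1))$median, 200)
  none <- median_survival(c(100, 200, 300), c(0, 0, 0))
  expect_false(none$reached)
  expect_true(is.na(none$median))
})

test_that("log-rank statistic matches the hand calculation and is symmetric", {
  # groups A: (1+, 3+), B: (2+, 4+), all events
  # O_A = 2, E_A = 1/2 + 1/3 + 1/2 = 4/3, V = 1/4 + 2/9 + 1/4 = 13/18
  # chisq = (2 - 4/3)^2 / (13/18) = (4/9) / (13/18) = 8/13
  lr <- logrank_test(c(1, 3, 2, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 8 / 13, tolerance = 1e-12)
  expect_equal(lr$df, 1)
  expect_equal(lr$p, pchisq(8 / 13, 1, lower.tail = FALSE), tolerance = 1e-12)

  same <- logrank_test(c(5, 9, 5, 9), c(1, 0, 1, 0), c("A", "A", "B", "B"))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  swap <- logrank_test(c(1, 3, 2, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(swap$chisq, lr$chisq, tolerance = 1e-12)
})

test_that("AUC equals Mann-Whitney concordance with half credit for ties", {
  sep <- roc_auc(c(10, 9, 8, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                         FALSE))
  expect_equal(sep$auc, 1)
  # responders {3,1}, non-responders {2,0}: 3 of 4 pairs concordant
  toy <- roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(toy$auc, 0.75)
  # oracle equivalence with the normalized Mann-Whitney U, with ties
  set.seed(21)
  sc <- sample(1:8, 60, replace = TRUE)
  lab <- rep(c(TRUE, FALSE), 30)
  u <- unname(suppressWarnings(
    wilcox.test(sc[lab], sc[!lab])$statistic))
  expect_equal(roc_auc(sc, lab)$auc, u / (sum(lab) * sum(!lab)),
               tolerance = 1e-12)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both")
})

test_that("logistic remission model recovers coefficients and flags edge cases", {
  set.seed(8)
  n <- 4000
  pred <- runif(n, 0, 100)
  ipi <- sample(0:5, n, TRUE)
  y <- rbinom(n, 1, plogis(0.5 + 0.02 * pred - 0.4 * ipi)) == 1
  fit <- multivariate_remission_fit(pred, ipi, remission = y)
  expect_false(fit$separation)
  expect_equal(unname(fit$coefficients["prediction"]), 0.02, tolerance = 0.25)
  expect_equal(unname(fit$coefficients["ipi"]), -0.4, tolerance = 0.25)
  expect_lt(fit$p_one_sided["prediction"], 0.01)
  expect_lt(fit$p_one_sided["ipi"], 0.01)

  # constant IPI is inestimable, not an error
  fit2 <- multivariate_remission_fit(pred, rep(2L, n), remission = y)
  expect_true("ipi" %in% fit2$inestimable)
  expect_true(is.na(fit2$coefficients["ipi"]))

  # complete separation triggers the flagged ridge fallback
  pred3 <- 1:20
  y3 <- pred3 > 10
  expect_warning(
    fit3 <- multivariate_remission_fit(pred3, rep_len(0:5, 20),
                                       remission = y3),
    "ridge")
  expect_true(fit3$separation)
  expect_identical(fit3$method, "ridge")
  expect_gt(unname(fit3$coefficients["prediction"]), 0)
})

test_that("summary table has the endpoint x method layout with sane p-values", {
  co <- simulate_patient_cohort(cohort_sim_params(seed = 4))
  sig <- response_signature("CHOP", data.frame(
    feature_id = co$truth$planted_features, selection_correlation = 0.6))
  ss <- score_cohort(co$expr, sig, co$clinical)
  tab <- summary_table(ss, co$clinical)
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(rownames(tab), c("Remission", "Overall survival",
                                "Progression-free survival"))
  expect_equal(colnames(tab), c("Prediction", "IPI", "Combined", "GCB_ABC"))
  vals <- tab[, 1:3]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(is.na(tab[, "GCB_ABC"])))   # no subtype scores supplied
  gcb <- rnorm(nrow(ss))
  tab2 <- summary_table(ss, co$clinical, gcb_abc = gcb)
  expect_true(all(tab2[, "GCB_ABC"] >= 0 & tab2[, "GCB_ABC"] <= 1))
})
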