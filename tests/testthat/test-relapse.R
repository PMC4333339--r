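# 6-patient relapse cohort over the tiny two-regimen panel
tiny_expr <- function() {
  set.seed(17)
  make_expr(matrix(rnorm(24, mean = 7), 4, 6),
            features = c("mir01", "mir02", "mir03", "mir04"),
            samples = sprintf("P%02d", 1:6))
}

test_that("relapse score is the mean of received regimens' normalized scores", {
  expr <- tiny_expr()
  panel <- make_tiny_panel()
  mat <- regimen_score_matrix(expr, panel)
  expect_equal(dim(mat), c(2L, 6L))
  expect_equal(unname(apply(mat, 1, range)), matrix(c(0, 100, 0, 100), 2))

  rs <- relapse_scores(expr, list(P01 = "AAA", P02 = c("AAA", "BBB")), panel)
  expect_equal(unname(rs["P01"]), unname(mat["AAA", "P01"]))  # mean of one
  expect_equal(unname(rs["P02"]),
               mean(mat[c("AAA", "BBB"), "P02"]))
  # permutation-invariant in the received list
  rs2 <- relapse_scores(expr, list(P02 = c("BBB", "AAA")), panel)
  expect_equal(unname(rs2["P02"]), unname(rs["P02"]))
  expect_error(relapse_scores(expr, list(P01 = "XYZ"), panel), "XYZ")
})

test_that("two regimens with normalized scores 40 and 60 average to 50", {
  mat <- rbind(A = c(40, 0, 100), B = c(60, 100, 0))
  colnames(mat) <- c("p1", "p2", "p3")
  # construct expression so single-feature signatures reproduce mat exactly
  expr <- make_expr(mat, features = c("fA", "fB"), samples = colnames(mat))
  panel <- regimen_panel(
    A = response_signature("A", data.frame(feature_id = "fA",
                                           selection_correlation = 0.5)),
    B = response_signature("B", data.frame(feature_id = "fB",
                                           selection_correlation = 0.5)))
  rs <- relapse_scores(expr, list(p1 = c("A", "B")), panel)
  expect_equal(unname(rs), 50)
})

test_that("cutoff optimization attains the exhaustive grid maximum", {
  # two well-separated clusters, low scores die first
  scores <- c(10, 11, 12, 80, 81, 82, 83)
  times <- c(30, 40, 50, 800, 900, 1000, 1100)
  events <- rep(1, 7)
  oc <- optimize_cutoff(scores, times, events, min_group = 3)
  expect_gt(oc$cutoff, 12)
  expect_lt(oc$cutoff, 80)
  expect_true(oc$data_optimized)
  expect_match(oc$note, "descriptive")

  # oracle: exhaustive search over all eligible midpoints
  u <- sort(unique(scores))
  cands <- (u[-1] + u[-length(u)]) / 2
  cands <- cands[vapply(cands, function(cc)
    sum(scores >= cc) >= 3 && sum(scores < cc) >= 3, TRUE)]
  chis <- vapply(cands, function(cc)
    logrank_test(times, events, scores >= cc)$chisq, numeric(1))
  expect_equal(oc$chisq, max(chis), tolerance = 1e-12)
  expect_true(logrank_test(times, events, scores >= oc$cutoff)$chisq >=
                max(chis) - 1e-12)

  expect_error(optimize_cutoff(scores[1:5], times[1:5], events[1:5],
                               min_group = 3), "at least")
})

test_that("fixed_n mode labels exactly the requested number sensitive", {
  scores <- c(5, 30, 42, 55, 60, 71, 90)
  oc <- optimize_cutoff(scores, rexp(7), rep(1, 7), mode = "fixed_n",
                        n_sensitive = 3)
  expect_equal(sum(scores >= oc$cutoff), 3)
  expect_true(oc$data_optimized)
})

test_that("relapse survival comparison reports per-group medians", {
  scores <- c(80, 85, 90, 10, 20, 30)
  times <- c(1000, 1100, 1200, 100, 200, 300)
  events <- rep(1, 6)
  cmp <- compare_relapse_survival(scores, 50, times, events)
  med <- cmp$medians
  expect_equal(med$median[med$group == "sensitive"], 1100)
  expect_equal(med$median[med$group == "resistant"], 200)
  expect_false(cmp$data_optimized)
  expect_error(compare_relapse_survival(rep(90, 6), 50, times, events),
               "one predicted group")

  oc <- optimize_cutoff(scores, times, events, min_group = 3)
  cmp2 <- compare_relapse_survival(scores, oc, times, events)
  expect_true(cmp2$data_optimized)
  expect_match(cmp2$note, "descriptive")
})

test_that("regimen recommendations rank descending with alphabetical ties", {
  expr <- make_expr(rbind(c(8, 0, 4), c(2, 10, 4)),
                    features = c("fA", "fB"), samples = c("p1", "p2", "p3"))
  sigA <- response_signature("A", data.frame(feature_id = "fA",
                                             selection_correlation = 0.5))
  sigB <- response_signature("B", data.frame(feature_id = "fB",
                                             selection_correlation = 0.5))
  rec <- recommend_regimens(expr, regimen_panel(A = sigA, B = sigB),
                            cutoff = 50)
  p1 <- rec[rec$patient_id == "p1", ]
  expect_equal(p1$regimen, c("A", "B"))
  expect_equal(p1$normalized_score, c(100, 0))
  expect_equal(p1$call, c("sensitive", "resistant"))
  # identical signatures -> identical scores, ties broken alphabetically
  rec2 <- recommend_regimens(expr, regimen_panel(B = sigA, A = sigA))
  expect_equal(rec2$regimen[rec2$patient_id == "p1"], c("A", "B"))
  expect_error(regimen_panel(), "at least one")
})

test_that("biopsy concordance counts diagonal balance and handles degeneracy", {
  x <- c(a = 10, b = 20, c = 30, d = 40)
  same <- biopsy_concordance(x, x)
  expect_equal(same$r, 1)
  expect_equal(same$n_on_diagonal, 4)
  expect_equal(same$n_above + same$n_below, 0)

  y <- c(a = 40, b = 32, c = 21, d = 8)
  anti <- biopsy_concordance(x, y)
  expect_equal(anti$r, pearson_oracle(unname(x), unname(y)),
               tolerance = 1e-12)
  expect_lt(anti$r, 0)

  one <- biopsy_concordance(c(a = 1), c(a = 2))
  expect_true(is.na(one$r))   # correlation undefined for a single pair
  expect_equal(one$n_above, 1)
})
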