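test_that("expression matrix reader preserves shape, ids and missingness", {
  path <- write_tsv_fixture(c("feature_id\tS1\tS2",
                              "mirA\t1.5\t2.5",
                              "mirB\tNA\t0",
                              "mirC\t-3\t4.25"))
  m <- read_expression_matrix(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(rownames(m), c("mirA", "mirB", "mirC"))
  expect_equal(colnames(m), c("S1", "S2"))
  expect_true(is.na(m["mirB", "S1"]))     # missing stays missing, never 0
  expect_identical(m["mirB", "S2"], 0)
  expect_identical(m["mirC", "S2"], 4.25)
})

test_that("reader errors name the duplicate id and locate bad cells", {
  dup <- write_tsv_fixture(c("feature_id\tS1\tS2",
                             "mirA\t1\t2", "mirA\t3\t4"))
  expect_error(read_expression_matrix(dup), "mirA")
  bad <- write_tsv_fixture(c("feature_id\tS1\tS2",
                             "mirA\t1\t2", "mirB\toops\t4"))
  expect_error(read_expression_matrix(bad), "mirB.*S1|S1.*mirB")
})

test_that("expression matrices round-trip through tsv and csv", {
  m <- make_expr(matrix(c(1.25, NA, -2, 7, 0, 3.5), 3, 2))
  for (dialect in c("tsv", "csv")) {
    path <- tempfile()
    write_expression_matrix(m, path, dialect)
    expect_equal(read_expression_matrix(path, dialect), m)
  }
})

test_that("GI50 reader stores -log10 molar and passes neg_log10 through", {
  molar <- write_tsv_fixture(c("drug\tC1\tC2\tC3",
                               "dox\t1e-6\t1e-5\t1e-7"))
  p1 <- read_gi50_table(molar, scale = "gi50_molar")
  expect_equal(unname(p1["dox", ]), c(6, 5, 7))
  neg <- write_tsv_fixture(c("drug\tC1\tC2\tC3",
                             "dox\t6\t5\t7"))
  p2 <- read_gi50_table(neg, scale = "neg_log10")
  expect_equal(p1, p2)   # equivalent encodings yield identical panels
  zero <- write_tsv_fixture(c("drug\tC1\tC2\tC3", "dox\t0\t1e-5\t1e-7"))
  expect_error(read_gi50_table(zero, scale = "gi50_molar"), "positive")
})

test_that("drug response panel enforces its invariants", {
  expect_error(drug_response_panel(matrix(c(1, NA, NA, NA), 1, 4,
                                          dimnames = list("d", paste0("c", 1:4)))),
               "fewer than 3")
  expect_error(drug_response_panel(matrix(Inf, 1, 3,
                                          dimnames = list("d", paste0("c", 1:3)))),
               "finite")
})

test_that("clinical table validation accepts good rows and rejects bad ones", {
  cl <- make_clinical()
  expect_s3_class(cl, "patient_records")
  path <- tempfile(fileext = ".csv")
  write_clinical_table(cl, path)
  back <- read_clinical_table(path)
  expect_equal(as.data.frame(back), as.data.frame(cl))

  # response matched case-insensitively to the canonical label
  low <- as.data.frame(cl); low$response[1] <- "cru"
  expect_equal(patient_records(low)$response[1], "CRu")

  bad_ipi <- as.data.frame(cl); bad_ipi$ipi[2] <- 6L
  expect_error(patient_records(bad_ipi), "0..5")
  bad_resp <- as.data.frame(cl); bad_resp$response[1] <- "remission"
  expect_error(patient_records(bad_resp), "CRu")   # lists allowed labels
  bad_t <- as.data.frame(cl)
  bad_t$pfs_days[2] <- bad_t$os_days[2] + 10
  bad_t$os_event[2] <- bad_t$pfs_event[2] <- TRUE
  expect_error(patient_records(bad_t), "pfs_days exceeds os_days")
})

test_that("signatures round-trip and corrupt files are rejected", {
  sig <- response_signature("CHOP",
                            data.frame(feature_id = c("a", "b"),
                                       selection_correlation = c(0.41, 0.3)),
                            threshold = 0.25)
  path <- tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$treatment_name, "CHOP")
  expect_equal(back$threshold, 0.25)
  expect_equal(back$entries[c("feature_id", "selection_correlation")],
               sig$entries[c("feature_id", "selection_correlation")])

  corrupt <- write_tsv_fixture(c("# treatment=CHOP", "# threshold=0.25",
                                 "feature_id\tselection_correlation",
                                 "a\t0.10"))
  expect_error(read_signature(corrupt), "threshold")
})

test_that("signature constructor rejects duplicates and empty entry lists", {
  expect_error(response_signature("x", data.frame(
    feature_id = c("a", "a"), selection_correlation = c(0.4, 0.5))),
    "duplicate")
  expect_error(response_signature("x", data.frame(
    feature_id = character(0), selection_correlation = numeric(0))),
    "at least one")
})

test_that("alignment intersects in cohort order and reports drops", {
  expr <- make_expr(matrix(1:6, 2, 3), samples = c("A", "B", "C"))
  cl <- make_clinical(3)
  cl$patient_id <- c("B", "C", "D")
  al <- align_cohort(expr, cl)
  expect_equal(colnames(al$expr), c("B", "C"))
  expect_equal(al$clinical$patient_id, c("B", "C"))
  expect_equal(al$dropped_samples, "A")
  expect_equal(al$dropped_patients, "D")

  cl2 <- make_clinical(3); cl2$patient_id <- c("A", "B", "C")
  al2 <- align_cohort(expr, cl2)
  expect_length(al2$dropped_samples, 0)
  expect_length(al2$dropped_patients, 0)

  cl3 <- make_clinical(2); cl3$patient_id <- c("X", "Y")
  expect_error(align_cohort(expr, cl3), "overlap")
})

test_that("split_regimens handles empty and multi-entry strings", {
  out <- split_regimens(c("", "DHAP", "ICE; DHAP", NA))
  expect_equal(out, list(character(0), "DHAP", c("ICE", "DHAP"),
                         character(0)))
})
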