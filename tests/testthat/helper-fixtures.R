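# Small in-code fixtures shared across test files.

make_expr <- function(values, features = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(features)) features <- sprintf("mir%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  expression_matrix(m, features, samples)
}

make_clinical <- function(n = 4, ...) {
  base <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    ipi = rep_len(c(1L, 3L, 0L, 5L), n),
    treatment = rep_len("R-CHOP", n),
    response = rep_len(c("CR", "PR", "CRu", "PD"), n),
    os_days = rep_len(c(1000, 400, 1200, 150), n),
    os_event = rep_len(c(FALSE, TRUE, FALSE, TRUE), n),
    pfs_days = rep_len(c(1000, 300, 1200, 100), n),
    pfs_event = rep_len(c(FALSE, TRUE, FALSE, TRUE), n),
    relapse = rep_len(FALSE, n),
    relapse_regimens = rep_len("", n),
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  patient_records(base)
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a tiny two-regimen panel over disjoint planted features
make_tiny_panel <- function() {
  regimen_panel(
    AAA = response_signature("AAA", data.frame(
      feature_id = c("mir01", "mir02"), selection_correlation = c(0.5, 0.4))),
    BBB = response_signature("BBB", data.frame(
      feature_id = c("mir03", "mir04"), selection_correlation = c(0.6, 0.3)))
  )
}

# textbook product-moment correlation, kept independent of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
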