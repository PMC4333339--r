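Package: mirsens
Title: MicroRNA Signatures of Chemosensitivity for Lymphoma Treatment
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds microRNA response signatures for combination
    chemotherapy regimens by correlating baseline cell-line expression
    with summed -log10(GI50) drug-sensitivity vectors, scores patient
    tumor expression profiles against those signatures (equal-weight
    mean, 0-100 linear normalization, combination with the
    International Prognostic Index), validates predictions against
    remission and survival endpoints (one-sided Wilcoxon, Kaplan-Meier
    and log-rank, ROC/AUC, multivariate logistic remission models),
    ranks alternative second/third-line regimens for relapse patients,
    and simulates synthetic cell-line panels and patient cohorts with
    planted signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    pROC,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
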