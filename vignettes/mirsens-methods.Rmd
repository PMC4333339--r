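---
title: "Methods: microRNA chemosensitivity signatures, scoring, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microRNA chemosensitivity signatures, scoring, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsens)
```

## The problem

Diffuse large B-cell lymphoma (DLBCL) patients receive combination
chemotherapy (R-CHOP or R-CHOEP) in first line; most respond, but patients
who relapse face many second/third-line options and a much lower response
probability. `mirsens` implements a translational strategy for choosing
among regimens: learn which microRNAs mark *in vitro* sensitivity to a drug
combination on a screened cancer cell-line panel, then read those microRNAs
out of a patient's tumor biopsy (FFPE material, where microRNA is far more
stable than mRNA) to predict that patient's sensitivity to the same
combination.

## Signature construction

The in-vitro inputs are a drug-response panel (per-drug $-\log_{10}(GI_{50})$
vectors over a shared set of cell lines; higher = more sensitive) and the
cell lines' baseline log2 microRNA expression.

For a combination of drugs $d_1,\dots,d_k$ the per-cell-line sensitivity is
the *unweighted sum*

$$ s_c = \sum_{j=1}^{k} \big(-\log_{10} GI_{50}(d_j, c)\big), $$

with no z-scoring before summation; a cell line enters only if it has a
value for every component drug (`combination_sensitivity_vector()`). Each
expression feature $g$ is then correlated with $s$ over the shared cell
lines (Pearson, pairwise-complete), and the signature keeps the features
with

$$ r_g > \tau, \qquad \tau = 0.25 \text{ by default.} $$

Three conventions matter and are fixed in `select_signature()`:

* the inequality is **strict** ("above 0.25"; a tie at exactly 0.25 is
  excluded);
* only **positively** correlated features are eligible — higher expression
  marks sensitivity; negatively correlated features carry no predictive
  power in this setting and a panel with only negative correlations is an
  error, not an empty signature;
* entries are sorted by feature id, so the same inputs always produce the
  identical signature object.

Feature identifiers are opaque strings; array probe-set suffixes such as
`_st` / `_x_st` are kept verbatim. The packaged 20-feature CHOP signature
(`chop_signature()`) stores each feature's strongest single-agent
correlation as its `selection_correlation` because the combined-assay value
was never published; the single-agent and remission correlations are
carried as annotation columns.

## Scoring patients

Every signature feature gets equal weight: a sample's **raw prediction
score** is the mean of the signature features' log2 expression values. A
sample missing some signature features is scored as the mean over the
non-missing ones, with a warning — equal weighting degrades gracefully.

Raw scores are mapped to a 0–100 scale by the min–max linear transform over
the scored cohort,

$$ s' = 100\,\frac{s - \min(s)}{\max(s) - \min(s)}, $$

the most literal reading of a "linear transformation of the prediction
score of all patient samples". The division happens before the scaling by
100 so the extremes are *exactly* 0 and 100 in floating point. The
normalization population defaults to the patient's treatment arm (each
regimen's profile is normalized over the patients who received that
regimen); `norm_population = "cohort"` pools everyone.

The **combination score** folds in the International Prognostic Index:

$$ \text{Combined} = \text{Prediction} - 25 \times \text{IPI}. $$

The weight 25 makes the IPI term's range over IPI $0..5$ equal to 125,
comparable to the prediction score's range of 100, i.e. roughly equal
weight for the molecular and the clinical component.

Classification uses `score >= cutoff` → sensitive (default cutoff 50). The
boundary case is deliberately assigned to "sensitive": the source
convention says only "above and below", so one side had to be chosen and
documented; tests pin it.

`quantile_normalize_log2()` is a convenience for raw positive intensity
matrices (quantile mapping, then log2). It is a generic quantile stand-in,
not RMA; the package's contract is pre-normalized log2 input, and the
function says so in its message.

## Validation statistics

Responses are coded ordinally CR = 5, CRu = 4, PR = 3, SD = 2, PD = 1, Dead
(before response evaluation) = 0; Unevaluable records are always excluded.
Responders are CR + CRu by default (`"cr_only"` reproduces the CR-vs-rest
comparison). Dead-before-evaluation patients are *included* as
non-responders by default — they appear in the response analyses — with
`include_dead = FALSE` available as a sensitivity analysis, since deaths
from toxicity are not disease progression.

* **Wilcoxon** (`wilcoxon_one_sided()`): one-sided rank-sum, responders
  hypothesized higher; exact enumeration when $n_1+n_2 \le 20$ and the data
  are untied, otherwise the normal approximation with tie and continuity
  correction. Two groups with no variation at all return $p = 1$.
* **Response correlation** (`response_correlation()`): Pearson correlation
  between score and the ordinal codes, one-sided $p$ from the $t$
  distribution with $n-2$ df. The ordinal spacing (1 unit per category) is
  a convention; any strictly monotone coding gives the same sign, and the
  spacing used is the simplest one consistent with the category order.
* **Survival** (`km_curve()`, `median_survival()`, `logrank_test()`):
  product-limit estimates via the survival package with log–log confidence
  intervals, default level 0.90 (configurable); median = earliest time with
  $S(t) \le 0.5$, reported "not reached" when the curve never gets there.
  Overall survival runs from diagnosis to death of any cause;
  progression-free survival to progression or death. Log-rank is the
  standard $k-1$ df statistic; a dataset with no events returns
  $\chi^2 = 0$, $p = 1$ rather than an error.
* **ROC/AUC** (`roc_auc()`): curve over all distinct thresholds (pROC); the
  trapezoidal AUC equals the Mann–Whitney concordance probability with half
  credit for ties, and the tests assert that equivalence against a
  pair-counting oracle.
* **Multivariate remission model** (`multivariate_remission_fit()`):
  logistic regression `remission ~ A*Prediction + B*IPI (+ C*GCB/ABC)` fit
  by maximum likelihood. The link is a design choice — remission is binary
  and the published coefficient magnitudes are compatible with a logistic
  fit; the printed A:B ratio cannot discriminate between linear and
  logistic links given rounding. One-sided Wald p-values test the
  hypothesized directions (A > 0, B < 0, C > 0). Covariates without
  variation are reported inestimable rather than raising an error; complete
  separation is detected, flagged, and refit with a small ridge penalty
  (hand-rolled IRLS with the penalized Hessian supplying standard errors)
  so a coefficient and a descriptive interval still come back.
* **Summary table** (`summary_table()`): rows Remission / OS / PFS, columns
  Prediction / IPI / Combined / GCB-ABC. Remission cells are one-sided
  Wilcoxon p-values (the IPI enters negated because low IPI is favorable);
  survival cells are log-rank p-values at each method's dichotomization:
  prediction at 50, IPI at the standard high-risk split $\ge 3$, the
  combined score at its cohort median (it has no canonical cutoff; the
  median split is the symmetric default and is configurable), GCB/ABC at 0
  (the natural sign boundary between the subtypes). No multiple-testing
  correction is applied across cells, matching the analysis the table
  reproduces.

The GCB/ABC subtype score is `mean(GCB features) − mean(ABC features)`;
profile contents are supplied by the user (`subtype_profile()`), since the
published 8- and 10-microRNA subtype profiles are external inputs.

## Relapse treatment selection

A relapse patient's score against the treatment they actually received is
the mean of the per-regimen normalized scores of their second/third-line
regimens. Per-regimen scores are normalized 0–100 **across the relapse
cohort being analyzed** — the normalization population for relapse analyses
is not fixed by the source setting, and the relapse cohort itself is the
only population in which all regimen scores exist for all patients.

`optimize_cutoff()` splits the relapse cohort at the cutoff maximizing the
two-group log-rank $\chi^2$ over all midpoints of consecutive sorted unique
scores, requiring at least `min_group = 3` patients per side (degenerate
splits on cohorts of a dozen patients are otherwise easy to hit). Ties are
broken toward the candidate nearest the median score. Because the cutoff is
chosen to maximize separation, p-values computed at it are *descriptive,
not valid tests*; every result derived from an optimized cutoff carries a
machine-readable `data_optimized = TRUE` flag and a note saying exactly
that. A second mode, `fixed_n`, instead picks the cutoff that labels a
requested number of patients sensitive (useful when re-analyzing with
diagnostic instead of relapse biopsies while holding group sizes fixed).

`recommend_regimens()` scores every panel regimen on every patient and
ranks descending, breaking score ties alphabetically so rankings are stable
and deterministic. `biopsy_concordance()` reports the Pearson correlation of
paired primary/relapse scores plus the counts above, below, and on the
identity diagonal; with fewer than 3 pairs the correlation is reported
undefined.

## The synthetic-data generator

All generators are pure functions of their parameter objects (seed
included). The panel model, per cell line $c$:

$$ s_c \sim N(0,1), \qquad
   -\log_{10}GI_{50}(d, c) = \beta_d\, s_c + \varepsilon_{dc}, \qquad
   x_{gc} = 7 + \gamma\, s_c\,[g \in \text{planted}] + \eta_{gc}, $$

with defaults of 60 cell lines, 1756 features, 20 planted features,
loadings $\beta = (0.6, 0.6, 0.1)$ for vincristine / doxorubicin /
cyclophosphamide, and $\gamma = 0.8$. The near-zero cyclophosphamide
loading reflects its biology: it is a prodrug activated in the liver, so
its in-vitro GI50 spread across cell lines is small (~3-fold) and it
contributes little to the combination signature.

Two noise scales are distinguished deliberately. Log2 expression
measurement noise defaults to SD 1.0, a typical residual scale for array
intensities. The GI50 assay noise defaults to SD 0.6 per drug on the
$-\log_{10}$ scale — assay replicate error, a physically different quantity
from cross-sample expression noise. At these defaults the planted features'
single-agent correlations average about 0.45 for the two active drugs and
0.07 for cyclophosphamide, the scale observed in real vin/dox-dominated
signatures, and their correlation with the summed vector is about 0.49, so
the 0.25-threshold selection recovers planted features with recall ~0.97
while nulls leak in at the analytic $t$-tail rate
$P(r > 0.25 \mid n = 60) \approx 0.027$ (so a default signature carries a
realistic fringe of false features around the planted core).

The cohort model, per patient $p$: latent sensitivity $s_p \sim N(0,1)$
drives the same planted features; the ordinal response latent is

$$ u_p = a_1 s_p - a_2\,\text{IPI}_p + e_p, \qquad e_p \sim N(0,1), $$

thresholded into Dead / PD / SD / PR / CRu / CR. Defaults $a_1 = 0.5$,
$a_2 = 0.4$ were calibrated once, before any test was written, so that the
synthetic cohort's score–response correlation (~0.3), the one-sided
Wilcoxon power, and the relative strength of prediction, IPI and combined
score resemble the clinical behavior the pipeline targets; they were not
revisited afterwards. The category thresholds are frozen constants,
quantile-calibrated at those defaults to the emulated cohort's category
frequencies (57 CR, 42 CRu, 5 PR, 0 SD, 2 PD, 5 dead-before-evaluation of
111 evaluable among 116, with 5 unevaluable). The SD interval has zero
width because the emulated cohort contained no stable-disease responses; SD
remains a recognized input category.

Survival is exponential with hazard
$\lambda_0 \exp(0.25\,\text{IPI} + 1.5\,[\text{non-responder}])$,
$\lambda_0 = 10^{-4}$/day, under uniform censoring on 400–2500 days,
yielding roughly the emulated death fraction (~20%) at a median observation
around 1300 days; progression uses the same linear predictor at a lower
baseline, and PFS $\le$ OS holds by construction. Dead-before-evaluation
patients get early observed deaths (20–120 days). Responding patients
relapse with probability 0.12 and receive 1–2 regimens from
COPE/DHAP/CVP/HDMTX/MVBCNS; each regimen has its own planted feature block
driven by an independent per-patient regimen sensitivity, and post-relapse
survival hazard decreases in the mean regimen match of the received
regimens — so relapse scoring, cutoff optimization and survival comparison
all have recoverable planted structure.

Matched biopsy pairs (`simulate_relapse_cohort()`) add independent
per-feature noise (default SD 1.0) to the primary biopsy with no
systematic drift, so paired scores scatter symmetrically about the
diagonal.

**What the generator does not emulate:** batch effects, probe-level array
artifacts, FFPE degradation, correlated feature blocks (co-expressed
microRNA clusters), non-Gaussian tails, and realistic biopsy-pair
attenuation — because the 20-feature mean averages away the per-feature
drift, synthetic pair correlations (~0.97) are far higher than the ~0.4
seen between real primary and relapse biopsies, where tumors actually
evolve. Passing tests therefore demonstrate that the pipeline's machinery
is correct and well calibrated under its stated model, not that the
signature generalizes to real tumors.

## Test and simulation sizes

The test suite uses 50-seed recovery runs at full panel size (60 × 1756),
1000-replicate null suites for the type-I calibration of Wilcoxon,
log-rank and the response correlation (3 binomial SEs around 0.05), a
100-seed Wald-coverage check for the logistic remission model, and a
50-seed AUC power-ordering comparison — sizes chosen to make the binomial
noise bands tight relative to the properties being asserted while the whole
suite stays interactive (seconds, not minutes).

## Known limitations

* Min–max normalization makes every score cohort-relative: a patient's
  0–100 score changes when the cohort changes, and the two extreme
  patients' scores are pinned by construction.
* The optimized relapse cutoff is descriptive; with a dozen patients a
  validated cutoff would need an external cohort.
* Equal-weight scoring is the method, not an option; no attempt is made to
  learn feature weights, and the package deliberately offers nothing for it.
* The multivariate model's link choice (logistic) is an interpretation;
  coefficient magnitudes are therefore not directly comparable to fits made
  under a linear-probability reading.
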