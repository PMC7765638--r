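---
title: "Methods: rule-based PCOS phenotyping, evaluation and PRS association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based PCOS phenotyping, evaluation and PRS association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcospectrum)
```

## The problem

Polycystic ovary syndrome (PCOS) is a common endocrine disorder whose
diagnostic criteria are contested and whose symptoms — oligo/anovulation,
hyperandrogenism, polycystic ovarian morphology — occur across a severity
spectrum. In electronic health records (EHRs), a research cohort has to be
assembled from diagnosis codes and clinical notes rather than from a
clinical examination. `pcospectrum` implements a family of four *nested*
rule-based phenotyping algorithms that sweep from a strict, high-precision
definition to a broad, high-recall one, together with the machinery to
evaluate them (chart-review metrics), to characterise the resulting cohorts
clinically (cleaned, age-adjusted lab values), and to validate them
genetically (polygenic risk score association).

Because the clinical data such analyses run on are access-restricted, the
package also ships a synthetic EHR generator with a known ground truth, so
every stage of the pipeline is testable end to end.

## The phenotyping algorithms

All algorithms operate on females aged 11–44 and share three ICD9/ICD10
code sets:

* **polycystic ovaries** — 256.4 (ICD9), E28.2 (ICD10);
* **hirsutism** (coded evidence of hyperandrogenism) — 704.1, L68.0;
* **irregular menses** — the whole 626.x ICD9 family, the whole N91.x
  ICD10 family, plus N92.5 and N92.6.

From strictest to broadest:

| algorithm | inclusion logic | keyword required |
|---|---|---|
| `keyword_strict` | PCO **or** (hirsutism **and** irregular menses) | yes |
| `coded_strict`   | PCO **or** (hirsutism **and** irregular menses) | no |
| `keyword_broad`  | PCO **or** hirsutism **or** irregular menses | yes |
| `coded_broad`    | PCO **or** hirsutism **or** irregular menses | no |

Any exclusion code (conditions that mimic PCOS: congenital adrenal
hyperplasia, Cushing syndrome, androgen-secreting neoplasm,
hyperprolactinemia, thyroid dysfunction — shipped as a clearly marked
placeholder list, configurable via YAML) removes a patient from every case
set. The keyword requirement demands at least one of "polycystic ovaries",
"PCOS" or "PCO" in a note whose type belongs to a six-entry whitelist
(outpatient note, gynecology clinic visit, nursing report, endocrine and
diabetes clinic visit, pediatric endocrinology patient visit, reproductive
endocrinology clinic visit). **Controls** carry neither an exclusion code
nor *any* inclusion code. By construction the four case sets are nested
and controls are disjoint from all of them; `build_cohorts()` is tested
against a brute-force recount on the generator's ground-truth flags.

### Design choices that were genuinely open

* **Keyword matching semantics.** Only the keyword strings are specified
  by the design, not how they match. The default is case-insensitive
  *token* matching: "PCOS"/"PCO" must appear as whole alphanumeric tokens
  (so "pcostatin" never fires) and "polycystic ovaries" matches as a
  whitespace-normalised phrase. A `mode = "substring"` flag provides the
  laxer alternative; tests cover both.
* **Age reference point.** "Aged 11–44" has no stated reference time. The
  default assesses age at the most recent code event (a patient's current
  record age); `age_basis = "any_event"` accepts patients whose record
  ever intersects the window.
* **Control purity.** The control rule is code-based only; a patient whose
  notes mention PCOS but who carries no inclusion code remains a control.
* **Family codes.** "All 626 codes"/"all N91 codes" are prefix matches on
  the printed code string, within the correct ICD version, dots included.

## Evaluation

`confusion_metrics()` computes PPV, NPV, sensitivity and specificity as
exact ratios from a 2×2 of algorithm versus gold-standard labels;
`pct_int()` renders them as integer percents (round half away from zero),
and `pct_2sf()`/`prevalence()` render EHR prevalence to two significant
figures, the two conventions used in published tables of this kind.
`ppv_from_review()` reproduces chart-review PPV (reviewer-confirmed true
positives over reviewed charts). The sensitivity/specificity evaluation
frame defaults to the *medical home* population (codes on ≥ 5 separate
days spanning ≥ 3 years) intersected with a *data floor* (≥ 1 ICD10 E28.2
code), mirroring how review charts are drawn in practice; both filters are
exported and configurable. Metrics with a zero denominator are explicit
`NA`s, never silent zeros. Wilson intervals are available but kept out of
the table-reproduction output.

## Laboratory pipeline

`clean_lab_table()` applies, in order: drop non-numeric raw values; drop
analytes observed in only one patient; drop exact duplicate rows; keep
only each analyte's modal unit; collapse to the per-patient median. Each
drop reason is counted. `trim_percentile_outliers()` then removes values
strictly outside the (1st, 99th) percentile band of the per-patient-median
distribution — trimming operates on the medians, the unit entering
analysis, and percentile bounds use linear interpolation (R quantile
type 7); the strict-exclusion reading (values *at* the percentile survive)
is deliberate and documented here because an inclusive reading is equally
defensible. Distributions with fewer than 10 values are left untrimmed
with a warning.

`age_adjust_inverse_normal()` regresses the per-patient median on the
median age at measurement (consistent with median aggregation) and maps
the OLS residuals through a rank-based inverse normal transformation with
Blom offsets, `z = qnorm((r − 3/8)/(n + 1/4))`, average ranks for ties.
The offset choice is essentially immaterial: alternatives change `z` by
less than 0.03 for n > 100. Zero age variance downgrades to transforming
raw values with a warning. BMI is taken from recorded BMI rows, or derived
as kg/m² from same-day weight/height pairs with heights sanity-bounded to
[1.2, 2.2] m.

## Association models

`rank_sum_test()` performs the two-sided Wilcoxon rank-sum comparison of
case versus control lab distributions: exact enumeration when the pooled
sample is ≤ 20 without ties, otherwise the normal approximation with tie
and continuity corrections (delegated to `stats::wilcox.test`; an
independent brute-force enumerator in the test suite verifies every group
split up to n = 10).

`logistic_prs_assoc()` fits case status on the PRS by maximum-likelihood
logistic regression (IRLS, relative tolerance 1e-8, 100-iteration cap,
with explicit separation detection). The PRS is standardised to unit SD
*within the analysis sample*, so effects are odds ratios per SD;
confidence intervals are Wald (matching the symmetric interval columns of
conventional PRS tables), and variance explained is Nagelkerke's
pseudo-R², `[1 − (L0/L1)^{2/n}] / [1 − L0^{2/n}]`. Covariates default to
median age and ten genetic principal components. `match_cases_controls()`
supplies age/race-matched control sets — the matching ratio (1:4) and
age-bin width (5 years) are not dictated by the design and are exposed as
arguments; controls are re-matched per algorithm. `linear_prs_assoc()`
is the OLS analogue for the inverse-normal-transformed hormones, with the
PRS partial R² computed as the R² difference against the covariates-only
model.

`correction_thresholds()` always computes Bonferroni bounds exactly as
α/m. Note that for α = 0.05 and m = 120 the bound is 4.2 × 10⁻⁴; rounding
conventions sometimes quote thresholds near 4 × 10⁻³ for test counts of
this order, which is an order of magnitude looser than α/m — the package
never substitutes such a rounded value. Benjamini–Hochberg FDR control is
exposed via `bh_reject()`.

## The synthetic EHR generator

`generate_population()` emulates the statistical structure the analysis
assumes; it is a study-conditions generator, not a realism engine.

* **Population**: configurable size; stratum weights 0.567 / 0.115 /
  0.043 / 0.275 for NH White / NH African American / Hispanic /
  other-unknown, matching the population mix such analyses report; birth
  dates uniform over ages 11–44 at the reference date; 2% non-female
  records to exercise the eligibility filter.
* **Genetics and liability**: PRS ~ N(0, 1); ten pure-noise PCs; ancestry
  follows stratum (African American → AFR, else EUR). True case status is
  Bernoulli with logit `qlogis(0.065) + log(1.3)·PRS` — a base rate of
  6.5% and an odds ratio of 1.3 per SD. The logistic (rather than
  Gaussian-threshold) liability makes the OR-per-SD target exact by
  construction, which is what the parameter-recovery tests estimate.
* **Severity coupling**: a case's symptom probabilities rise linearly in
  its liability percentile (e.g. P(polycystic-ovaries code) = 0.35 +
  0.40·severity), as does keyword documentation. This single mechanism
  produces the two qualitative signatures the tests check: stricter
  algorithm tiers select more severe cases, so median BMI and fitted PRS
  odds ratios both increase with stringency. Under a null configuration
  (`beta_prs = 0`) the liability is flat, severity degenerates to ½, and
  symptoms decouple from the PRS — giving the null pipeline a valid
  type-I error, which is verified over 400 replicates.
* **Labs**: log-normal (strictly positive, right-skewed), control medians
  24.03 kg/m² (BMI), 13.65 mcU/mL (insulin), 55.5 pg/mL (estradiol),
  3.0 pg/mL (free testosterone), with severity-dependent location shifts
  calibrated so strict-tier case BMI medians land near 34 kg/m²; small
  stratum offsets; rare non-numeric values ("QNS"), discordant units, and
  same-day weight/height pairs exercise the cleaning chain. Analyte draws
  are independent given case status — within-patient hormone correlation
  is deliberately not modelled and is a config knob, not a claim.
* **Distractors**: "pcostatin"-style near-miss notes and PCOS mentions in
  non-whitelisted note types exercise tokenisation and the whitelist.
* **Reproducibility**: one RNG substream per component (demographics,
  genetics, symptoms, events, notes, labs), all derived from a single
  root seed, so outputs are byte-identical given (config, seed) and
  editing one sub-model leaves the others unchanged.

What passing tests on this generator do **not** show: performance on real
EHR data, with its coding drift, documentation habits, correlated
comorbidities and informative missingness. The generator's ground truth
stands in for human chart review; agreement rates against it measure the
pipeline's logic, not clinical accuracy.

## Problem sizes and numerical choices

The shipped tests run the nesting property over 20 seeds at n = 10 000
patients, parameter recovery at 2000 cases / 5000 controls over 50 seeds,
the null type-I study at n = 1200 over 400 replicates, and the
stringency-pattern checks over 10 seeds at n = 12 000 — sizes chosen so
the full suite exercises every claim at meaningful power while remaining
comfortable to run on a laptop. Dates use a 365.25-day year throughout;
"5 separate days" means distinct calendar dates and "3-year period" means
last-minus-first ≥ 1095.75 days; duplicate identical code events are
collapsed before counting days. Percentiles and quartiles use linear
interpolation everywhere.

## Known limitations

* No negation detection or section parsing in notes — keyword presence is
  taken at face value, exactly as the rule-based design specifies.
* The exclusion code set is a placeholder; deploying against real data
  requires the institution's own list.
* The generator does not model longitudinal visit dynamics, medications,
  or code co-occurrence beyond the modelled symptoms.
* Race/ethnicity strata with unknown race are retained in totals but
  excluded from race-stratified analyses.
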