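---
title: "Preoperative mortality risk scores for liver resection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preoperative mortality risk scores for liver resection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepascore)
```

## The problem

Ninety-day mortality after hepatectomy is the endpoint that preoperative
risk scores in liver surgery are judged against. This package implements
three such scores as exact calculators and the statistical machinery
used to validate and compare them on a patient-level cohort, together
with a seeded synthetic cohort generator so that the whole pipeline is
exercisable and testable without access to protected patient data.

## The three scores

### Mortality Risk Score

An additive preoperative score over eight factors. One point each for
age ≥ 60 years, right trisectionectomy, INR ≥ 1.1 and GGT ≥ 60 U/l; two
points for platelets < 120/nl; three points for creatinine ≥ 2 mg/dl;
histology contributes 1 point for intrahepatic and 2 for perihilar
cholangiocarcinoma; ASA III contributes 1 and ASA IV 5 points. The
maximum is therefore 16. Points map to six groups: 0–1 → 1 (very
low-risk), 2 → 2A, 3 → 2B (low-risk), 4 → 3A, 5 → 3B (medium-risk),
≥ 6 → 4 (high-risk).

Every "≥" threshold is inclusive and the platelet threshold strict,
exactly as the score defines them; the boundary behaviour is pinned by
unit tests (age 60.0 scores the point, platelets 120 does not score).
ASA V is outside the score's definition and is rejected as a domain
error rather than extrapolated. Missing values in a scored field are
an error — no imputation anywhere in the package, because silent
imputation would corrupt validation tables; batch scoring routes such
rows to an explicit rejects table instead (`score_cohort()`).

### labMELD

$$\mathrm{labMELD} = 10\,(0.957\,\ln c + 0.378\,\ln b + 1.120\,\ln i + 0.643)$$

with creatinine $c$ (mg/dl, capped at 4, forced to 4 under dialysis),
bilirubin $b$ (mg/dl) and INR $i$; each component floored at 1 before
the logarithm; the result rounded to the nearest integer and clamped to
[6, 40]. The attainable minimum is $10 \times 0.643 = 6.43 \to 6$.

The rounding of half-integers is not pinned down by the verbal
definition; we round halves up, the convention of the UNOS allocation
MELD from which the formula descends. Ties at .5 are measure-zero for
continuous inputs and the unrounded value is available via
`labmeld(..., round = FALSE)` for auditing. Values above 40 are
clamped down to 40, again the MELD convention.

### P-POSSUM

Twelve physiological items and six operative items are graded 1/2/4/8
by the original POSSUM banding tables (Copeland's system); the grades
sum to the physiological score PS ∈ [12, 96] and operative severity
score OS ∈ [6, 48], and the Portsmouth mortality equation is

$$\ln\frac{R}{1-R} = -9.065 + 0.1692\,PS + 0.1550\,OS.$$

The banding tables are shipped as a plain-text, versioned data file
(`inst/extdata/possum_bands.csv`) and loaded at run time, so the
transcription is auditable and replaceable; pre-graded items can always
be passed directly, so no downstream computation depends on the
transcription. Numeric bands are matched after snapping the raw value
to the table's printed resolution (1 unit, or 0.1 for haemoglobin,
white cells, urea and potassium), which gives the printed closed ranges
a defined meaning for values quoted at higher precision; a value
outside all bands for its item is a named domain error.

For elective hepatectomy cohorts the operative severity item is
conventionally "major". `possum_operative_score(force_major = TRUE)`
floors the severity grade at 4 rather than overwriting it, so a
genuine "major+" (grade 8) case is never downgraded — the floor
interpretation preserves information while honouring the convention.

## Validation statistics

All validation statistics are implemented from the definitions; the
standard library routines (`fisher.test`, `wilcox.test`, `glm`, pROC)
appear only as independent oracles in the test suite.

* **Stratified mortality tables** (`stratified_mortality_table()`): one
  row per stratum with n, events, percent, the cross-product odds ratio
  versus the reference stratum (risk-score reference: group 1; labMELD
  reference: score 6), the Woolf log-normal 95% CI, and the two-sided
  Wald p of the stratum-vs-reference logistic model. For a saturated
  2×2 logistic model the ML slope is exactly $\ln \mathrm{OR}$ with the
  Woolf standard error, so the p-value is computed in closed form; the
  equivalence with the iterative fit is property-tested. Zero cells
  receive the Haldane–Anscombe +0.5 correction and are flagged; empty
  strata are emitted with n = 0 and flagged, never dropped.
* **Fisher's exact test**: two-sided p by the point-probability method
  (sum of hypergeometric probabilities not exceeding the observed
  table's), matched exhaustively against an independent factorial-ratio
  enumeration for every 2×2 table with total ≤ 30.
* **Mann-Whitney U**: midrank U; exact p by enumeration of the
  permutation distribution when $nm \le 400$ *and* the number of group
  assignments is itself enumerable (≤ 2×10⁵ — the product $nm$ alone
  does not bound the enumeration size), otherwise the tie-corrected
  normal approximation with continuity correction.
* **Logistic regression** (`fit_logistic()`): Newton–Raphson with
  step-halving, convergence at a maximum coefficient update below
  1e-8 within 100 iterations, covariance from the inverse observed
  information. Complete separation is detected (diverging
  coefficients with degenerate fitted probabilities) and flagged, not
  raised. Rank-deficient designs are errors.
* **C-index / ROC** (`c_index()`, `roc_curve()`): the rank formula
  (ties count half), which provably equals both the Mann-Whitney
  identity $U/(n_1 n_0)$ and the trapezoidal area under the ROC
  staircase; both identities are property-tested to 1e-12.
* **Paired AUC comparison** (`compare_scores()`): DeLong's paired test
  by default. The SAS "Wald test from the underlying logistic models"
  wording that motivates this comparison is ambiguous; as the
  documented alternative, `method = "wald"` uses the two per-curve
  DeLong variances without the pairing covariance — a conservative
  unpaired Wald z. The choice is a config switch end to end (CLI flag
  `--roc-test`).

No multiplicity adjustment is applied anywhere (two-sided α = 0.05),
matching standard practice for this kind of single-cohort score
comparison.

## The synthetic cohort generator

`generate_cohort()` emulates the case mix of a large tertiary-centre
hepatectomy series (n = 529 by default). What it reproduces, and how:

* **Factor prevalences** (defaults): trisectionectomy 7.4%,
  intrahepatic CC 11.2%, perihilar CC 6.6%, INR ≥ 1.1 11.5%,
  GGT ≥ 60 53.9%, platelets < 120 6.0%, creatinine ≥ 2 1.3%,
  bilirubin ≥ 2 6.2%, ASA III+IV 45.9%. The ASA III/IV split is not
  published; we use IV = 1.9% (a realistic share for elective
  hepatectomy) and III = 44.0%.
* **Age**: a reflected log-normal, $100 - \mathrm{age} \sim LN$,
  hitting median 61.8 and IQR 52.8–69.0 years. The reflection gives
  the left skew of surgical age distributions: the printed quartiles
  are almost exactly log-symmetric around the median after reflection
  about 100, and P(age ≥ 60) ≈ 0.559 follows analytically.
* **Labs**: log-normal with fixed medians (INR 1.0, GGT 65 U/l,
  platelets 220/nl, creatinine 0.85 mg/dl, bilirubin 0.6 mg/dl) and
  the log-sd *solved* so that the threshold exceedance probability
  equals the specified prevalence. Binary factors are then derived by
  thresholding the stored continuous values, so thresholds and
  prevalences are mutually consistent by construction. An infeasible
  combination (median on the wrong side of the threshold for the
  requested prevalence) is rejected before sampling.
* **Outcome**: each record is scored, then death is Bernoulli with its
  risk group's rate (0.5, 0.8, 6.1, 9.1, 9.4, 40.0%). The group-rate
  mechanism (rather than a smooth logistic in points) makes
  stratum-table validation exactly recoverable in expectation.
* **POSSUM items**: i.i.d. categorical over {1, 2, 4, 8} with
  probabilities chosen to give mean PS ≈ 17.1 and mean OS ≈ 16.2 (the
  published cohort means), the severity item drawn from
  {major, major+}.
* **Reproducibility**: one root seed; every variable draws from its
  own substream (root seed × fixed multiplier + per-variable offset,
  kept below 2³¹), so adding a variable never perturbs earlier
  streams. Same `(seed, spec)` → byte-identical CSV.

What the generator deliberately does **not** emulate: correlations
between factors (beyond the deterministic ties above), temporal
trends, centre effects, and missingness. Independence is the simplest
structure consistent with every published marginal, but it is also the
generator's most visible departure from real data: in the real cohort
the risk factors cluster (perihilar tumours get trisectionectomies and
have high GGT and bilirubin), inflating both tails of the point
distribution. Under independence the implied group mix — computable
exactly by convolving the component distributions, see
`expected_death_rate()` — places less mass in the extreme groups, and
the expected overall death rate is 3.9% rather than the 4.5% of the
published mix. A cohort of 529 at the generator's rate is still
statistically consistent with observing 24/529 deaths (z ≈ 0.8), and
the acceptance suite tests exactly that; but passing tests on
generated cohorts demonstrates the correctness of the calculators and
statistics, not that the generator reproduces the joint distribution
of any real cohort.

`reconstruct_printed_cohort()` is different in kind: it
deterministically expands published stratum counts (six risk-score
groups with 193/130/99/55/32/20 patients and 1/1/6/5/3/8 deaths; six
labMELD levels with 236/148/57/41/28/19 and 4/5/4/2/4/5) into
patient-level records, enabling *exact* recomputation of the printed
percentages, odds ratios and Wald p-values. The C-index from these
reconstructions is approximate by construction: the published values
(0.8421 for the risk score, 0.7352 for labMELD) used the unbinned
scores, while the reconstruction collapses "0+1" and the open-ended
top strata to single levels. The binned values (0.840, 0.733) land
within 0.01, and the residual is binning, not error. The published
AUCs for PS, OS and the P-POSSUM mortality % (0.6953, 0.5413, 0.6795)
and the pairwise ROC p-values cannot be recomputed at all without the
patient-level data; they are covered by the property suite (identities
and oracle agreements) instead of point assertions.

A note on the published risk-score odds-ratio column: the labMELD
stratum ORs reproduce exactly as cross-products of their own counts
(2.03, 4.38, 2.97, 9.67, 20.71 — and even the printed p-values match
the closed-form Wald test), which validates the estimator. The
risk-score stratum ORs (0.50 … 43.33) do *not* reproduce from that
table's own counts under any standard 2×2 estimator (group 4 vs 1
gives 128.0); they presumably originate in the score's development
cohort. We implement the estimator the labMELD table proves correct
and document the discrepancy rather than guessing.

## Problem sizes and numerical choices

The test suite runs in well under a minute on one CPU: the Fisher
cross-check enumerates all 46 375 tables with total ≤ 30; the
C-index/Mann-Whitney identity runs over 1000 random cohorts; the
generator checks use 100 cohorts of n = 529 plus single cohorts of
n = 2×10⁴–10⁵; the labMELD property sweep uses 10⁵ random inputs and
the P-POSSUM oracle grid all 85 × 43 (PS, OS) pairs. Tolerances are
1e-12 for exact identities (rank/trapezoid, logistic oracle), 1e-9 for
the labMELD formula against an independently coded evaluation, 1e-6
for iterative-vs-closed-form logistic equivalences, and 3 standard
errors for statistical recovery.

Internal computation is always at full precision; rounding (one
decimal for percentages, two for odds ratios) happens only when report
tables are rendered. The inverse logit is evaluated in its
numerically stable branch form. Integer score arithmetic uses exact
integer types throughout.

## Known limitations

* The generator's independence assumption understates the tails of the
  score distribution (discussed above).
* The Copeland banding transcription covers the standard items; exotic
  local modifications of POSSUM grading are out of scope, though the
  band file is designed to be replaced.
* Only binary 90-day mortality is modelled; no survival-time methods,
  no calibration statistics (Hosmer–Lemeshow), and no E-PASS/
  Child–Turcotte–Pugh comparators.
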