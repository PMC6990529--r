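# hepascore

Preoperative mortality risk scores for liver resection, and the
statistics to validate them.

Deciding whether a patient should undergo hepatectomy increasingly
relies on preoperative risk scores for 90-day mortality. This package
is for surgeons, trialists and methodologists who need those scores as
exact, auditable calculators and who want to run (or re-run) the
standard internal-validation analysis on a patient-level cohort. It
implements:

* **Mortality Risk Score** — an additive 0–16-point score over eight
  preoperative factors (age ≥ 60, right trisectionectomy, INR ≥ 1.1,
  GGT ≥ 60 U/l score 1 each; platelets < 120/nl scores 2; creatinine
  ≥ 2 mg/dl scores 3; intrahepatic/perihilar cholangiocarcinoma score
  1/2; ASA III/IV score 1/5), stratified into groups
  1, 2A, 2B, 3A, 3B, 4.
* **labMELD** —
  `10·(0.957 ln creatinine + 0.378 ln bilirubin + 1.120 ln INR + 0.643)`,
  with the creatinine cap at 4 mg/dl (forced under dialysis),
  component floors at 1, integer rounding, range 6–40.
* **P-POSSUM** — the Portsmouth mortality equation
  `logit(R) = −9.065 + 0.1692·PS + 0.1550·OS` over the POSSUM
  physiological (PS) and operative severity (OS) scores, including the
  original 1/2/4/8 item banding tables for grading raw measurements.
* **Validation statistics, from first principles** — stratified
  mortality tables with cross-product odds ratios (Woolf CIs, Wald
  p-values), Fisher's exact test, Mann-Whitney U, Newton–Raphson
  logistic regression, ROC curves, the C-index, and DeLong's paired
  AUC comparison.
* **A seeded synthetic cohort generator** emulating a tertiary-centre
  hepatectomy case mix, plus deterministic reconstructions of
  published stratum-count tables for exact recomputation of stratum
  statistics.

## Worked example

Score a single patient and validate the scores on a synthetic cohort:

```r
library(hepascore)

rec <- list(age_years = 65, right_trisectionectomy = TRUE, inr = 1.2,
            ggt_u_per_l = 100, platelets_per_nl = 150,
            creatinine_mg_dl = 1.0, diagnosis = "perihilar_cc",
            asa_class = 3)
mortality_risk_points(rec)
#> Mortality Risk Score (1 record)
#>   age trisectionectomy inr ggt platelets creatinine diagnosis asa points group
#> 1   1                1   1   1         0          0         2   1      7     4
#>   description
#> 1   high-risk

labmeld(1.1, 1.8, 1.3)                     # integer score
#> [1] 13
round(100 * ppossum_mortality(18, 17), 1)  # predicted mortality, %
#> [1] 3.3

coh <- generate_cohort(cohort_spec(n = 529, seed = 42))
sc  <- score_cohort(coh)$scored
score_validation(sc)
#> Score validation: 529 patients, 28 events (5.3%)
#>
#>                 score    auc     se ci_low ci_high note
#>  Mortality Risk Score 0.8840 0.0261 0.8329  0.9351
#>               labMELD 0.5427 0.0539 0.4369  0.6484
#>           PS/P-POSSUM 0.5456 0.0489 0.4497  0.6414
#>           OS/P-POSSUM 0.6064 0.0627 0.4835  0.7293
#>  P-POSSUM mortality % 0.6131 0.0488 0.5174  0.7088
#>
#> Pairwise AUC comparisons vs Mortality Risk Score (delong):
#>                 score    auc difference  p_value
#>               labMELD 0.5427     0.3414 3.25e-09
#>           PS/P-POSSUM 0.5456     0.3385 2.99e-09
#>           OS/P-POSSUM 0.6064     0.2776 6.40e-05
#>  P-POSSUM mortality % 0.6131     0.2709 4.94e-06
```

The 7 points come from age (1) + trisectionectomy (1) + INR (1) +
GGT (1) + perihilar histology (2) + ASA III (1); group 4 is the
high-risk stratum. In the synthetic validation, only the risk score
discriminates strongly — by design: the generator draws deaths from
the risk-group rates, and the labs feed the other scores
independently of outcome (see the methods vignette).

Stratum statistics recomputed exactly from a published count table:

```r
coh <- reconstruct_printed_cohort("labmeld")
stratified_mortality_table(coh$labmeld_level, coh$death_90d, reference = "6")
#>  stratum n_total n_events pct_events odds_ratio ci_low ci_high  p_value
#>        6     236        4        1.7       1.00     NA      NA       NA
#>        7     148        5        3.4       2.03   0.54    7.68 2.98e-01
#>        8      57        4        7.0       4.38   1.06   18.07 4.12e-02
#>     9+10      41        2        4.9       2.97   0.53   16.79 2.17e-01
#>    11-14      28        4       14.3       9.67   2.27   41.14 2.14e-03
#>     >=15      19        5       26.3      20.71   5.00   85.79 2.92e-05
```

The odds ratios and p-values match the published table; binning the
score into levels puts the C-index at 0.733 (risk-score table: 0.840),
within 0.01 of the published unbinned values.

A thin command-line wrapper is included at `inst/cli/hepascore`
(`hepascore simulate|score|validate|compare-roc`).

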