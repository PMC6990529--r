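# Fixtures built in code: a baseline record with every score factor
# absent, and random score/outcome cohorts for property tests.

base_record <- function(...) {
  rec <- list(
    age_years = 40, sex = "male", asa_class = 1L, diagnosis = "other",
    right_trisectionectomy = FALSE, inr = 1.0, ggt_u_per_l = 30,
    platelets_per_nl = 250, creatinine_mg_dl = 0.8, bilirubin_mg_dl = 0.5,
    on_dialysis = FALSE
  )
  utils::modifyList(rec, list(...))
}

# record variants that switch on exactly one factor
factor_switches <- list(
  age = list(age_years = 60),
  trisectionectomy = list(right_trisectionectomy = TRUE),
  inr = list(inr = 1.1),
  ggt = list(ggt_u_per_l = 60),
  platelets = list(platelets_per_nl = 119),
  creatinine = list(creatinine_mg_dl = 2.0),
  diagnosis_i = list(diagnosis = "intrahepatic_cc"),
  diagnosis_p = list(diagnosis = "perihilar_cc"),
  asa3 = list(asa_class = 3L),
  asa4 = list(asa_class = 4L)
)

random_scored_cohort <- function(n, seed, p_event = 0.3, ties = TRUE) {
  set.seed(seed)
  scores <- if (ties) sample(1:8, n, replace = TRUE) else stats::rnorm(n)
  y <- stats::rbinom(n, 1L, p_event)
  # guarantee both classes
  if (sum(y) == 0L) y[1L] <- 1L
  if (sum(y) == n) y[1L] <- 0L
  list(scores = scores, y = y)
}

random_2x2 <- function(seed, max_total = 40, no_zero = FALSE) {
  set.seed(seed)
  repeat {
    cells <- stats::rmultinom(1, sample(4:max_total, 1), prob = stats::runif(4, 0.05, 1))[, 1]
    if (!no_zero || all(cells > 0)) return(cells)
  }
}
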