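test_that("the generator is deterministic under (seed, spec)", {
  spec <- cohort_spec(n = 200, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n = 200, seed = 8))
  expect_false(identical(a, c))
})

test_that("generated records satisfy every clinical invariant", {
  coh <- generate_cohort(cohort_spec(n = 2000, seed = 33))
  # scoring must succeed for every record (no missing/invalid fields)
  rs <- mortality_risk_points(coh)
  expect_identical(length(rs$points), 2000L)
  expect_true(all(coh$asa_class %in% 1:4))
  expect_true(all(coh$diagnosis %in% c("intrahepatic_cc", "perihilar_cc", "other")))
  expect_true(all(coh$inr > 0 & coh$creatinine_mg_dl > 0 & coh$bilirubin_mg_dl > 0))
  expect_true(all(coh$age_years >= 18 & coh$age_years <= 99))
  grades <- as.matrix(coh[, grep("^(ps|os)_", names(coh))])
  expect_true(all(grades %in% c(1, 2, 4, 8)))
  expect_identical(ncol(grades), 18L)
  expect_true(is.logical(coh$death_90d))
})

test_that("observed prevalences track the specification", {
  spec <- cohort_spec(n = 50000, seed = 3)
  coh <- generate_cohort(spec)
  se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  n <- nrow(coh)
  p <- spec$prevalence
  expect_lt(abs(mean(coh$right_trisectionectomy) - p["trisectionectomy"]),
            se3(p["trisectionectomy"], n))
  expect_lt(abs(mean(coh$inr >= 1.1) - p["inr_high"]), se3(p["inr_high"], n))
  expect_lt(abs(mean(coh$ggt_u_per_l >= 60) - p["ggt_high"]), se3(p["ggt_high"], n))
  expect_lt(abs(mean(coh$platelets_per_nl < 120) - p["platelets_low"]),
            se3(p["platelets_low"], n))
  expect_lt(abs(mean(coh$creatinine_mg_dl >= 2) - p["creatinine_high"]),
            se3(p["creatinine_high"], n))
  expect_lt(abs(mean(coh$diagnosis == "perihilar_cc") - p["perihilar_cc"]),
            se3(p["perihilar_cc"], n))
  expect_lt(abs(mean(coh$asa_class >= 3) - (p["asa3"] + p["asa4"])),
            se3(p["asa3"] + p["asa4"], n))
  # age law: median near 61.8, P(age >= 60) near its analytic value
  expect_lt(abs(stats::median(coh$age_years) - 61.8), 0.5)
  p60 <- hepascore:::prob_age_ge_60(spec)
  expect_lt(abs(mean(coh$age_years >= 60) - p60), se3(p60, n))
})

test_that("the death mechanism matches the closed-form mixture oracle", {
  spec <- cohort_spec(n = 20000, seed = 17)
  coh <- generate_cohort(spec)
  expected <- expected_death_rate(spec)
  # deaths are Bernoulli with group-specific rates; compare to the oracle
  expect_lt(abs(mean(coh$death_90d) - expected),
            4 * sqrt(expected * (1 - expected) / nrow(coh)))
  # group-conditional rates track the spec (largest two groups)
  rs <- mortality_risk_points(coh)
  for (g in c("1", "2A")) {
    idx <- rs$group == g
    r <- spec$group_death_rates[g]
    expect_lt(abs(mean(coh$death_90d[idx]) - r), 4 * sqrt(r * (1 - r) / sum(idx)))
  }
})

test_that("POSSUM score means sit near the published cohort means", {
  coh <- generate_cohort(cohort_spec(n = 20000, seed = 29))
  sc <- score_cohort(coh)$scored
  expect_lt(abs(mean(sc$ps) - 17.1), 0.5)
  expect_lt(abs(mean(sc$os) - 16.2), 0.5)
})

test_that("logistic regression recovers the implied group log-odds", {
  hits <- 0L
  for (s in 1:20) {
    spec <- cohort_spec(n = 5000, seed = 9000 + s)
    coh <- generate_cohort(spec)
    rs <- mortality_risk_points(coh)
    d <- data.frame(g = factor(as.character(rs$group)), y = coh$death_90d)
    fit <- fit_logistic(y ~ g, d)
    if (fit$separated) next
    rates <- spec$group_death_rates[levels(d$g)]
    truth <- c(log(rates[1] / (1 - rates[1])),
               log(rates[-1] / (1 - rates[-1])) - log(rates[1] / (1 - rates[1])))
    se <- sqrt(diag(vcov(fit)))
    if (all(abs(coef(fit) - truth) < 3 * se)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("infeasible specifications are rejected before sampling", {
  expect_error(cohort_spec(n = 0), class = "hepascore_validation_error")
  expect_error(cohort_spec(prevalence = c(ggt_high = 0.01)),
               class = "hepascore_validation_error")  # median above threshold
  expect_error(cohort_spec(prevalence = c(intrahepatic_cc = 0.7, perihilar_cc = 0.5)),
               class = "hepascore_validation_error")
  expect_error(cohort_spec(prevalence = c(nonsense = 0.5)),
               class = "hepascore_validation_error")
  expect_error(cohort_spec(group_death_rates = c("1" = 0.01)),
               class = "hepascore_validation_error")
})

test_that("printed-cohort reconstructions carry the published counts", {
  rs <- reconstruct_printed_cohort("risk_score")
  expect_identical(nrow(rs), 529L)
  expect_identical(sum(rs$death_90d), 24L)
  expect_identical(as.vector(table(rs$risk_group)), c(193L, 130L, 99L, 55L, 32L, 20L))
  lm <- reconstruct_printed_cohort("labmeld")
  expect_identical(nrow(lm), 529L)
  expect_identical(sum(lm$labmeld_level == ">=15"), 19L)
  expect_identical(sum(lm$death_90d[lm$labmeld_level == ">=15"]), 5L)
  # determinism
  expect_identical(rs, reconstruct_printed_cohort("risk_score"))
})

test_that("large-cohort C-index converges to the closed-form concordance", {
  spec <- cohort_spec(n = 100000, seed = 61)
  coh <- generate_cohort(spec)
  rs <- mortality_risk_points(coh)
  auc <- c_index(rs$points, coh$death_90d)
  # direct double sum over point levels from the exact point PMF
  pmf <- hepascore:::point_pmf(spec)
  rates <- spec$group_death_rates[as.character(risk_group(0:16))]
  p_death <- pmf * rates
  p_surv <- pmf * (1 - rates)
  num <- 0
  for (i in 0:16) for (j in 0:16) {
    w <- p_death[i + 1] * p_surv[j + 1]
    num <- num + w * ((i > j) + 0.5 * (i == j))
  }
  oracle <- num / (sum(p_death) * sum(p_surv))
  expect_lt(abs(auc - oracle), 0.01)
})
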