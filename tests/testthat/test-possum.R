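normal_phys <- list(age = 45, cardiac = "no_failure",
                    respiratory = "no_dyspnoea", sbp = 120, pulse = 70,
                    gcs = 15, hb = 14, wcc = 8, urea = 5, sodium = 140,
                    potassium = 4.2, ecg = "normal")
normal_oper <- list(severity = "minor", multiple = "one", blood_loss = 50,
                    soiling = "none", malignancy = "none", mode = "elective")

test_that("raw measurements map through the banding table", {
  g <- grade_physiology(normal_phys)
  expect_identical(unname(g), rep(1L, 12))
  expect_identical(possum_physiological_score(g), 12L)

  # age 65 is in the 61-70 band (grade 2), >= 71 is grade 4
  expect_identical(unname(grade_physiology(modifyList(normal_phys, list(age = 65)))["age"]), 2L)
  expect_identical(unname(grade_physiology(modifyList(normal_phys, list(age = 75)))["age"]), 4L)
  # an extreme band grades 8
  expect_identical(unname(grade_physiology(modifyList(normal_phys, list(sbp = 85)))["sbp"]), 8L)
  expect_identical(unname(grade_physiology(modifyList(normal_phys, list(potassium = 6.2)))["potassium"]), 8L)
  # operative side
  go <- grade_operative(modifyList(normal_oper, list(severity = "major", blood_loss = 600)))
  expect_identical(unname(go[c("severity", "blood_loss")]), c(4L, 4L))
})

test_that("ungradeable values and missing items are named errors", {
  expect_error(grade_physiology(modifyList(normal_phys, list(gcs = 2))),
               "gcs", class = "hepascore_domain_error")
  expect_error(grade_physiology(modifyList(normal_phys, list(ecg = "sinus"))),
               "ecg", class = "hepascore_domain_error")
  raw <- normal_phys; raw$urea <- NULL
  expect_error(grade_physiology(raw), "urea", class = "hepascore_schema_error")
  raw <- normal_oper; raw$mode <- NULL
  expect_error(grade_operative(raw), "mode", class = "hepascore_schema_error")
})

test_that("PS and OS are item sums with the documented severity floor", {
  expect_identical(possum_physiological_score(rep(1, 12)), 12L)
  expect_identical(possum_physiological_score(rep(8, 12)), 96L)
  expect_identical(possum_physiological_score(c(rep(1, 11), 4)), 15L)
  # operative severity forced to at least "major" (grade 4)
  expect_identical(possum_operative_score(rep(1, 6)), 9L)
  expect_identical(possum_operative_score(rep(1, 6), force_major = FALSE), 6L)
  expect_identical(possum_operative_score(rep(8, 6)), 48L)  # never downgraded
  named <- c(blood_loss = 1, severity = 1, multiple = 1, soiling = 1,
             malignancy = 1, mode = 1)
  expect_identical(possum_operative_score(named), 9L)  # severity found by name

  expect_error(possum_physiological_score(rep(1, 11)), class = "hepascore_domain_error")
  expect_error(possum_physiological_score(c(rep(1, 11), 3)), class = "hepascore_domain_error")
  expect_error(possum_operative_score(rep(5, 6)), class = "hepascore_domain_error")
})

test_that("scores equal brute-force sums for random item vectors", {
  set.seed(5)
  for (i in 1:25) {
    ps_items <- sample(c(1, 2, 4, 8), 12, replace = TRUE)
    os_items <- sample(c(1, 2, 4, 8), 6, replace = TRUE)
    expect_identical(possum_physiological_score(ps_items), as.integer(sum(ps_items)))
    expect_identical(possum_operative_score(os_items, force_major = FALSE),
                     as.integer(sum(os_items)))
  }
})

test_that("the mortality equation matches the logistic oracle and is monotone", {
  # frozen 50-digit oracle values
  expect_equal(ppossum_mortality(12, 6), 0.0022276009367467073, tolerance = 1e-14)
  expect_equal(ppossum_mortality(16, 17), 0.02359598223794241286, tolerance = 1e-14)
  expect_equal(ppossum_mortality(30, 20), 0.29131623542908644012, tolerance = 1e-14)
  expect_gt(ppossum_mortality(96, 48), 0.99)

  # independent oracle: stats::plogis on the linear predictor
  set.seed(21)
  ps <- sample(12:96, 200, replace = TRUE)
  os <- sample(6:48, 200, replace = TRUE)
  expect_equal(ppossum_mortality(ps, os),
               stats::plogis(-9.065 + 0.1692 * ps + 0.1550 * os),
               tolerance = 1e-15)

  # strict monotonicity in each argument
  expect_true(all(diff(ppossum_mortality(12:96, 20)) > 0))
  expect_true(all(diff(ppossum_mortality(40, 6:48)) > 0))
  expect_error(ppossum_mortality(11, 6), class = "hepascore_domain_error")
  expect_error(ppossum_mortality(12, 49), class = "hepascore_domain_error")
})
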