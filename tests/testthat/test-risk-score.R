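test_that("point awards match the published component definitions", {
  # every factor absent
  r0 <- mortality_risk_points(base_record())
  expect_identical(r0$points, 0L)
  expect_identical(as.character(r0$group), "1")
  expect_true(all(r0$components == 0L))

  # worked example: five single points + perihilar (2) + ASA III (1) = 7
  r7 <- mortality_risk_points(base_record(
    age_years = 65, right_trisectionectomy = TRUE, inr = 1.2,
    ggt_u_per_l = 100, platelets_per_nl = 150, creatinine_mg_dl = 1.0,
    diagnosis = "perihilar_cc", asa_class = 3L
  ))
  expect_identical(r7$points, 7L)
  expect_identical(as.character(r7$group), "4")
  expect_identical(r7$group_description, "high-risk")

  # worst case sums to the score maximum
  r16 <- mortality_risk_points(base_record(
    age_years = 80, right_trisectionectomy = TRUE, inr = 2.0,
    ggt_u_per_l = 300, platelets_per_nl = 80, creatinine_mg_dl = 3.0,
    diagnosis = "perihilar_cc", asa_class = 4L
  ))
  expect_identical(r16$points, 16L)
  expect_identical(as.character(r16$group), "4")
})

test_that("thresholds are inclusive exactly as defined", {
  pts <- function(...) mortality_risk_points(base_record(...))$points
  expect_identical(pts(age_years = 60), 1L)       # inclusive
  expect_identical(pts(age_years = 59.9), 0L)
  expect_identical(pts(inr = 1.1), 1L)
  expect_identical(pts(inr = 1.0999), 0L)
  expect_identical(pts(ggt_u_per_l = 60), 1L)
  expect_identical(pts(ggt_u_per_l = 59.9), 0L)
  expect_identical(pts(platelets_per_nl = 120), 0L)  # strict <
  expect_identical(pts(platelets_per_nl = 119.9), 2L)
  expect_identical(pts(creatinine_mg_dl = 2), 3L)
  expect_identical(pts(creatinine_mg_dl = 1.99), 0L)
})

test_that("points always equal the sum of awarded components", {
  set.seed(11)
  for (i in 1:50) {
    on <- factor_switches[sample(length(factor_switches), sample(0:6, 1))]
    args <- do.call(c, unname(on))
    rec <- if (is.null(args)) base_record() else do.call(base_record, args)
    r <- mortality_risk_points(rec)
    expect_identical(r$points, as.integer(sum(r$components)))
    expect_identical(as.character(r$group), as.character(risk_group(r$points)))
  }
})

test_that("switching any single factor on never decreases the points", {
  for (nm in names(factor_switches)) {
    base <- mortality_risk_points(base_record())$points
    flipped <- mortality_risk_points(do.call(base_record, factor_switches[[nm]]))$points
    expect_gt(flipped, base - 1L)  # i.e. >= base; all switches here add points
    expect_true(flipped >= base)
  }
})

test_that("missing or invalid scored fields are explicit errors", {
  rec <- base_record(); rec$inr <- NA_real_
  expect_error(mortality_risk_points(rec), "inr missing",
               class = "hepascore_schema_error")
  rec <- base_record(); rec$ggt_u_per_l <- NULL
  expect_error(mortality_risk_points(rec), "ggt_u_per_l missing")
  expect_error(mortality_risk_points(base_record(asa_class = 5L)),
               "ASA V", class = "hepascore_domain_error")
  expect_error(mortality_risk_points(base_record(diagnosis = "hcc")),
               class = "hepascore_domain_error")
})

test_that("risk group mapping follows the published point bands", {
  expect_identical(as.character(risk_group(c(0, 1))), c("1", "1"))
  expect_identical(as.character(risk_group(2:5)), c("2A", "2B", "3A", "3B"))
  expect_identical(as.character(risk_group(c(6, 10, 16))), c("4", "4", "4"))
  # monotone non-decreasing in points under the group order
  g <- risk_group(0:16)
  expect_true(all(diff(as.integer(g)) >= 0))
  expect_identical(risk_group_description(c("1", "2B", "3A", "4")),
                   c("very low-risk", "low-risk", "medium-risk", "high-risk"))
  expect_error(risk_group(-1), class = "hepascore_domain_error")
  expect_error(risk_group(2.5), class = "hepascore_domain_error")
  expect_error(risk_group(17), class = "hepascore_domain_error")
})
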