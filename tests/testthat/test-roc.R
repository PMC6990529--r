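test_that("C-index matches explicit pair enumeration", {
  # deaths scored {3, 5} vs survivors {1, 2, 3}: 5 wins + 1 tie of 6 pairs
  expect_equal(c_index(c(3, 5, 1, 2, 3), c(1, 1, 0, 0, 0)), 5.5 / 6,
               tolerance = 1e-12)
  # perfectly separating score
  expect_equal(c_index(c(10, 9, 1, 2), c(1, 1, 0, 0)), 1)
  # score carrying no information
  s <- random_scored_cohort(4000, seed = 1, p_event = 0.5)
  expect_lt(abs(c_index(stats::rnorm(4000), s$y) - 0.5), 0.05)
  expect_warning(expect_true(is.na(c_index(1:4, c(0, 0, 0, 0)))), "one outcome class")
})

test_that("C-index equals the Mann-Whitney identity and the ROC trapezoid", {
  for (i in 1:50) {
    s <- random_scored_cohort(sample(20:60, 1), seed = 3000 + i,
                              ties = i %% 2 == 0)
    auc <- c_index(s$scores, s$y)
    u <- mann_whitney_u(s$scores[s$y == 1], s$scores[s$y == 0], exact = FALSE)$u
    n1 <- sum(s$y); n0 <- sum(1 - s$y)
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)

    r <- roc_curve(s$scores, s$y)
    trap <- sum(diff(r$points$fpr) *
                (utils::head(r$points$sensitivity, -1) + utils::tail(r$points$sensitivity, -1)) / 2)
    expect_equal(trap, auc, tolerance = 1e-12)
    # staircase is monotone
    expect_true(all(diff(r$points$sensitivity) >= 0))
    expect_true(all(diff(r$points$fpr) >= 0))
  }
})

test_that("degenerate ROC shapes behave as constructed", {
  # perfectly separating score passes through (fpr 0, sens 1)
  r <- roc_curve(c(9, 8, 1, 2, 3), c(1, 1, 0, 0, 0))
  expect_true(any(r$points$fpr == 0 & r$points$sensitivity == 1))
  expect_equal(r$auc, 1)
  # single-valued score collapses to the diagonal
  r2 <- roc_curve(rep(3, 10), rep(c(0, 1), 5))
  expect_equal(r2$auc, 0.5)
  expect_equal(nrow(r2$points), 2L)
})

test_that("AUC and DeLong SE agree with pROC", {
  skip_if_not_installed("pROC")
  s <- random_scored_cohort(300, seed = 99, p_event = 0.25)
  r <- roc_curve(s$scores, s$y)
  ref <- pROC::roc(s$y, s$scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(r$auc_se^2, as.numeric(pROC::var(ref)), tolerance = 1e-12)
})

test_that("paired score comparison matches pROC's DeLong test", {
  skip_if_not_installed("pROC")
  set.seed(55)
  n <- 400
  y <- stats::rbinom(n, 1, 0.3)
  a <- y * 1.2 + stats::rnorm(n)
  b <- y * 0.4 + stats::rnorm(n)
  cmp <- compare_scores(a, b, y)
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(cmp$difference, as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
               tolerance = 1e-12)
})

test_that("comparing a score against itself gives difference 0 and p = 1", {
  s <- random_scored_cohort(100, seed = 12)
  cmp <- compare_scores(s$scores, s$scores, s$y)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  # permuting one score destroys its information
  set.seed(13)
  big <- random_scored_cohort(5000, seed = 14, p_event = 0.3)
  perm <- sample(big$scores)
  cmp2 <- compare_scores(big$scores, perm, big$y)
  expect_lt(abs(cmp2$auc_b - 0.5), 0.03)
  # the unpaired variant is never more significant than its own z implies
  cmp3 <- compare_scores(big$scores, perm, big$y, method = "wald")
  expect_gte(cmp3$se, 0)
  expect_error(compare_scores(1:4, 4:1, c(1, 1, 1, 1)),
               class = "hepascore_stats_error")
})
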