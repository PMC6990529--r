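# ROC analysis: concordance index by the rank formula, the ROC staircase
# with trapezoidal area, DeLong variances and the paired DeLong test for
# comparing two scores on the same patients.

#' Concordance index (C-index, AUC)
#'
#' Probability that a randomly chosen event carries a higher score than
#' a randomly chosen non-event, with ties counted half:
#' `(concordant + 0.5 * tied) / (n1 * n0)`.  Computed by the midrank
#' formula, so it equals the Mann-Whitney statistic of event vs
#' non-event scores divided by `n1 * n0`, and equals the trapezoidal
#' area under the ROC curve.
#'
#' @param scores Numeric risk scores (higher = more at risk).
#' @param outcomes Binary outcome (logical or 0/1); 1 = event.
#' @return AUC in [0, 1], or `NA` with a warning if either class is
#'   absent.
#' @examples
#' c_index(c(3, 5, 1, 2, 3), c(1, 1, 0, 0, 0))   # 0.9167
#' @export
c_index <- function(scores, outcomes) {
  y <- as_outcome(outcomes)
  if (!is.numeric(scores) || anyNA(scores) || length(scores) != length(y)) {
    stop_hepascore("validation", "scores must be numeric, non-missing, and match outcomes in length")
  }
  n1 <- sum(y); n0 <- sum(1 - y)
  if (n1 == 0L || n0 == 0L) {
    warning("only one outcome class present; AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 (one per event), V01 (one per non-event).
delong_placements <- function(scores, y) {
  sx <- scores[y == 1L]; sy <- scores[y == 0L]
  n1 <- length(sx); n0 <- length(sy)
  rx <- rank(c(sx, sy))[seq_len(n1)]
  v10 <- (rx - rank(sx)) / n0
  ry <- rank(c(sy, sx))[seq_len(n0)]
  v01 <- 1 - (ry - rank(sy)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

delong_var <- function(pl) {
  stats::var(pl$v10) / pl$n1 + stats::var(pl$v01) / pl$n0
}

#' ROC curve
#'
#' Operating points at every distinct score threshold (classification
#' rule: score >= threshold is called positive), from (0, 0) to (1, 1).
#' The trapezoidal area under the staircase equals the rank-formula
#' C-index exactly, including under ties (tied score blocks appear as
#' diagonal segments).
#'
#' @inheritParams c_index
#' @return Object of class `"hepascore_roc"`: `points` (data frame with
#'   `threshold`, `sensitivity`, `fpr`), `auc`, `auc_se` (DeLong),
#'   `n_events`, `n_nonevents`.  Methods: `print`, `plot`.
#' @export
roc_curve <- function(scores, outcomes) {
  y <- as_outcome(outcomes)
  auc <- c_index(scores, y)
  if (is.na(auc)) stop_hepascore("stats", "ROC curve undefined with a single outcome class")
  n1 <- sum(y); n0 <- sum(1 - y)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1L), numeric(1)) / n1
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L), numeric(1)) / n0
  pts <- data.frame(threshold = c(Inf, thr), sensitivity = c(0, sens),
                    fpr = c(0, fpr))
  pl <- delong_placements(scores, y)
  structure(list(points = pts, auc = auc, auc_se = sqrt(delong_var(pl)),
                 n_events = n1, n_nonevents = n0),
            class = "hepascore_roc")
}

#' @export
print.hepascore_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d events vs %d non-events, %d operating points\n",
              x$n_events, x$n_nonevents, nrow(x$points)))
  cat(sprintf("AUC (C-index): %.4f (DeLong SE %.4f)\n", x$auc, x$auc_se))
  invisible(x)
}

#' @export
plot.hepascore_roc <- function(x, add = FALSE, col = "black", lwd = 2, ...) {
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "Sensitivity", ...)
    graphics::abline(0, 1, col = "grey70", lty = 2)
  }
  graphics::lines(x$points$fpr, x$points$sensitivity, col = col, lwd = lwd, type = "s")
  invisible(x)
}

#' Compare the AUCs of two scores on the same patients
#'
#' Paired comparison of two risk scores evaluated on the same subjects
#' against the same binary outcome.  The default is DeLong's test: the
#' AUC difference divided by its standard error from the DeLong
#' placement-value covariance (accounting for the pairing), referred to
#' the normal distribution.  `method = "wald"` is a conservative
#' alternative that drops the pairing covariance and uses the two
#' per-curve DeLong variances alone.
#'
#' @param score_a,score_b Numeric scores for the same patients.
#' @param outcomes Binary outcome vector.
#' @param method `"delong"` (default) or `"wald"`.
#' @return List of class `"roc_comparison"`: `auc_a`, `auc_b`,
#'   `difference`, `se`, `z`, `p_value`, `method`.
#' @examples
#' set.seed(1)
#' y <- rbinom(100, 1, 0.3)
#' a <- y + rnorm(100); b <- rnorm(100)
#' compare_scores(a, b, y)
#' @export
compare_scores <- function(score_a, score_b, outcomes,
                           method = c("delong", "wald")) {
  method <- match.arg(method)
  y <- as_outcome(outcomes)
  if (length(score_a) != length(y) || length(score_b) != length(y)) {
    stop_hepascore("validation", "both scores must cover the same patients as the outcome")
  }
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop_hepascore("stats", "AUC comparison undefined with a single outcome class")
  }
  pa <- delong_placements(score_a, y)
  pb <- delong_placements(score_b, y)
  va <- delong_var(pa); vb <- delong_var(pb)
  if (method == "delong") {
    cov_ab <- stats::cov(pa$v10, pb$v10) / pa$n1 + stats::cov(pa$v01, pb$v01) / pa$n0
    v <- va + vb - 2 * cov_ab
  } else {
    v <- va + vb
  }
  d <- pa$auc - pb$auc
  se <- sqrt(max(v, 0))
  z <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
  structure(list(auc_a = pa$auc, auc_b = pb$auc, difference = d, se = se,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)), method = method),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.4f vs %.4f; difference %.4f (SE %.4f)\n",
              x$auc_a, x$auc_b, x$difference, x$se))
  cat(sprintf("%s test: z = %.3f, two-sided p = %.4g\n",
              if (x$method == "delong") "Paired DeLong" else "Unpaired Wald",
              x$z, x$p_value))
  invisible(x)
}
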