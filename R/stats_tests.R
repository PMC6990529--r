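# Elementary tests on 2x2 tables and two-sample comparisons, implemented
# directly so that every number in a validation table is reproducible
# from the definitions (the standard library routines serve as
# independent cross-checks in the test suite).

# Accept (a, b, c, d), a length-4 vector, or a 2x2 matrix (by row:
# a = events exposed, b = non-events exposed, c = events reference,
# d = non-events reference).
as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop_hepascore("domain", "need a 2x2 table")
    cells <- c(a[1, 1], a[1, 2], a[2, 1], a[2, 2])
  } else if (is.null(b) && length(a) == 4L) {
    cells <- a
  } else {
    cells <- c(a, b, c, d)
  }
  if (length(cells) != 4L || !is.numeric(cells) || anyNA(cells) ||
      any(cells < 0) || any(cells != round(cells))) {
    stop_hepascore("domain", "2x2 cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop_hepascore("domain", "2x2 table total must be positive")
  stats::setNames(as.numeric(cells), c("a", "b", "c", "d"))
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2x2 table, `(a*d)/(b*c)`, with the
#' Woolf (log-normal) confidence interval
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  If any cell is
#' zero, the Haldane-Anscombe correction (+0.5 to every cell) is applied
#' and flagged.  If a whole margin of the table is zero the odds ratio
#' is undefined even after correction and `NA` is returned with
#' `undefined = TRUE`.
#'
#' @param a,b,c,d Cell counts: events/non-events in the exposed stratum
#'   (`a`, `b`) and in the reference stratum (`c`, `d`).  Alternatively
#'   `a` may be a length-4 vector or 2x2 matrix (by row).
#' @param conf_level Confidence level for the Woolf interval.
#' @return List of class `"odds_ratio"`: `or`, `ci_low`, `ci_high`,
#'   `log_or`, `se_log_or`, `haldane` (correction applied?),
#'   `undefined`.
#' @examples
#' odds_ratio(5, 14, 4, 232)   # OR 20.71, as in a stratum-vs-reference table
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  t <- as_2x2(a, b, c, d)
  out <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              log_or = NA_real_, se_log_or = NA_real_,
              haldane = FALSE, undefined = FALSE)
  margins <- c(t["a"] + t["b"], t["c"] + t["d"], t["a"] + t["c"], t["b"] + t["d"])
  if (any(margins == 0)) {
    out$undefined <- TRUE
    class(out) <- "odds_ratio"
    return(out)
  }
  if (any(t == 0)) {
    t <- t + 0.5
    out$haldane <- TRUE
  }
  out$or <- (t["a"] * t["d"]) / (t["b"] * t["c"])
  out$log_or <- log(out$or)
  out$se_log_or <- sqrt(sum(1 / t))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out$ci_low <- exp(out$log_or - z * out$se_log_or)
  out$ci_high <- exp(out$log_or + z * out$se_log_or)
  out <- lapply(out, unname)
  class(out) <- "odds_ratio"
  out
}

#' @export
print.odds_ratio <- function(x, ...) {
  if (x$undefined) {
    cat("Odds ratio: undefined (zero margin)\n")
  } else {
    cat(sprintf("Odds ratio: %.4g (95%% CI %.4g-%.4g)%s\n", x$or, x$ci_low,
                x$ci_high, if (x$haldane) " [Haldane-Anscombe corrected]" else ""))
  }
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table
#' (the definition used by most statistical packages).  A table with an
#' all-zero margin carries no information and returns p = 1.
#'
#' @inheritParams odds_ratio
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact(3, 1, 1, 3)   # 0.4857
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- as_2x2(a, b, c, d)
  m <- t["a"] + t["b"]   # exposed row total
  n <- t["c"] + t["d"]   # reference row total
  k <- t["a"] + t["c"]   # event column total
  if (m == 0 || n == 0 || k == 0 || t["b"] + t["d"] == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(t["a"], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  unname(min(p, 1))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  U is computed from
#' midranks (ties count half).  The two-sided p-value is exact -- by
#' enumeration of the permutation distribution of U over all
#' reassignments of the pooled values -- when `n*m <= 400` and the
#' number of reassignments is itself enumerable (<= 2e5); otherwise the
#' tie-corrected normal approximation with continuity correction is
#' used.  The exact two-sided p is `P(|U - nm/2| >= |u_obs - nm/2|)`,
#' which by the symmetry of the permutation distribution equals the
#' usual doubled tail.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` applies the rule above.
#' @return List of class `"mann_whitney"`: `u` (statistic for `x`),
#'   `p_value`, `method` (`"exact"`/`"normal"`), `ties`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) == 0L || length(y) == 0L ||
      anyNA(x) || anyNA(y)) {
    stop_hepascore("validation", "both samples must be non-empty numeric vectors without NAs")
  }
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)               # midranks
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (length(unique(pooled)) == 1L) {
    warning("all values identical in both samples; p = 1")
    out <- list(u = u, p_value = 1, method = "degenerate", ties = TRUE)
    class(out) <- "mann_whitney"
    return(out)
  }

  n_comb <- choose(N, min(n, m))
  do_exact <- exact %||% (n * m <= 400 && n_comb <= 2e5)
  if (do_exact && n_comb > 2e5) {
    stop_hepascore("stats", "exact enumeration infeasible for these sample sizes")
  }

  if (do_exact) {
    idx <- utils::combn(N, n)
    u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    dev <- abs(u_all - n * m / 2)
    p <- mean(dev >= abs(u - n * m / 2) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    centred <- u - n * m / 2
    z <- (centred - sign(centred) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  out <- list(u = u, p_value = min(p, 1), method = method, ties = ties)
  class(out) <- "mann_whitney"
  out
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, two-sided p = %.4g (%s%s)\n",
              x$u, x$p_value, x$method, if (x$ties) ", ties" else ""))
  invisible(x)
}
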