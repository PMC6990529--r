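# Stratified validation of a risk score against binary 90-day mortality:
# per-stratum event rates, odds ratios vs a reference stratum, and an
# overall discrimination summary combining all scores.

#' Stratified mortality table
#'
#' One row per stratum, in the order of the factor levels: total n,
#' events, percent, cross-product odds ratio versus the reference
#' stratum with Woolf 95% CI, and the two-sided p-value of the Wald test
#' from the stratum-vs-reference logistic regression.  For a saturated
#' 2x2 logistic model the ML slope is exactly `ln(OR)` and its standard
#' error the Woolf SE, so the Wald z is computed in closed form as
#' `ln(OR) / sqrt(1/a + 1/b + 1/c + 1/d)` (the equivalence with
#' [fit_logistic()] is property-tested).  Zero cells receive the
#' Haldane-Anscombe correction and are flagged in `note`; empty strata
#' are emitted with `n_total = 0` and flagged, never dropped.
#'
#' @param strata Factor (or vector coercible to one) of stratum labels;
#'   level order defines the table order.
#' @param outcomes Binary outcome vector (1 = event).
#' @param reference Reference stratum label; defaults to the first
#'   level.  The reference row carries OR = 1 with an empty CI.
#' @return Data frame with columns `stratum`, `n_total`, `n_events`,
#'   `pct_events`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `note`.
#' @examples
#' coh <- reconstruct_printed_cohort("labmeld")
#' stratified_mortality_table(coh$labmeld_level, coh$death_90d)
#' @export
stratified_mortality_table <- function(strata, outcomes, reference = NULL) {
  if (!is.factor(strata)) strata <- factor(strata)
  y <- as_outcome(outcomes)
  if (length(strata) != length(y)) {
    stop_hepascore("validation", "strata and outcomes must have the same length")
  }
  reference <- as.character(reference %||% levels(strata)[1L])
  if (!reference %in% levels(strata)) {
    stop_hepascore("validation", sprintf("reference stratum '%s' not among levels", reference))
  }
  ref_events <- sum(y[strata == reference])
  ref_total <- sum(strata == reference)

  rows <- lapply(levels(strata), function(lev) {
    n <- sum(strata == lev)
    ev <- sum(y[strata == lev])
    row <- data.frame(stratum = lev, n_total = n, n_events = ev,
                      pct_events = if (n > 0) 100 * ev / n else NA_real_,
                      odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    if (lev == reference) {
      row$odds_ratio <- 1
      row$note <- "reference"
      return(row)
    }
    if (n == 0L) {
      row$note <- "empty stratum; OR undefined"
      return(row)
    }
    or <- odds_ratio(ev, n - ev, ref_events, ref_total - ref_events)
    if (or$undefined) {
      row$note <- "OR undefined (zero margin)"
      return(row)
    }
    row$odds_ratio <- or$or
    row$ci_low <- or$ci_low
    row$ci_high <- or$ci_high
    z <- or$log_or / or$se_log_or            # Wald z of the saturated logistic
    row$p_value <- 2 * stats::pnorm(-abs(z))
    if (or$haldane) row$note <- "Haldane-Anscombe corrected"
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' labMELD strata used for validation tables
#'
#' Bins integer labMELD scores into the conventional validation levels
#' `6`, `7`, `8`, `9+10`, `11-14`, `>=15` (reference level 6).
#'
#' @param labmeld Integer labMELD scores (6--40).
#' @return Ordered factor over the six levels.
#' @export
labmeld_level <- function(labmeld) {
  check_number(labmeld, "labmeld", lower = 6, upper = 40, integer = TRUE)
  lab <- ifelse(labmeld <= 8, as.character(labmeld),
         ifelse(labmeld <= 10, "9+10",
         ifelse(labmeld <= 14, "11-14", ">=15")))
  factor(lab, levels = c("6", "7", "8", "9+10", "11-14", ">=15"), ordered = TRUE)
}

#' Per-group distribution summary of comparator scores
#'
#' Median, IQR, mean and SD of one or more scores within each risk
#' group, plus a Kruskal-Wallis p-value across groups per score -- the
#' usual companion table when comparator scores are profiled along an
#' ordinal risk classification.
#'
#' @param data Data frame.
#' @param group_col Name of the grouping column (a factor).
#' @param score_cols Character vector of numeric score columns.
#' @return Data frame with one row per group x score.
#' @export
group_score_summary <- function(data, group_col = "risk_group", score_cols) {
  g <- data[[group_col]]
  if (is.null(g)) stop_hepascore("schema", sprintf("%s missing", group_col))
  if (!is.factor(g)) g <- factor(g)
  out <- list()
  for (sc in score_cols) {
    v <- data[[sc]]
    if (is.null(v)) stop_hepascore("schema", sprintf("%s missing", sc))
    kw <- stats::kruskal.test(v, g)$p.value
    for (lev in levels(g)) {
      x <- v[g == lev]
      out[[length(out) + 1L]] <- data.frame(
        score = sc, group = lev, n = length(x),
        median = stats::median(x),
        q1 = unname(stats::quantile(x, 0.25)),
        q3 = unname(stats::quantile(x, 0.75)),
        mean = mean(x), sd = stats::sd(x),
        p_value = kw, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Validate risk scores against 90-day mortality
#'
#' The package's central analysis: given a scored cohort, computes for
#' every selected score its ROC curve, AUC (C-index) with a 95% CI from
#' the DeLong standard error, and a paired comparison against the
#' reference score; plus the stratified mortality tables for the risk
#' score groups and the labMELD levels, and the per-group distribution
#' summary of the comparator scores.
#'
#' @param data Data frame containing the score columns and the outcome.
#'   Typically the output of [score_cohort()] on a cohort with
#'   outcomes.
#' @param scores Named character vector mapping display labels to column
#'   names.  Defaults to whichever of `risk_points`, `labmeld`, `ps`,
#'   `os`, `ppossum_pct` are present.
#' @param outcome Name of the binary outcome column.
#' @param reference Label of the reference score for pairwise AUC
#'   comparisons (default: the first score).
#' @param roc_test `"delong"` or `"wald"`, passed to
#'   [compare_scores()].
#' @return Object of class `"score_validation"` with elements `auc`
#'   (data frame), `comparisons`, `rocs` (list of
#'   [roc_curve()] objects), `table_risk`, `table_labmeld`,
#'   `group_summary`, `n`, `n_events`.  Methods: `print`, `summary`,
#'   `plot`.
#' @export
score_validation <- function(data, scores = NULL, outcome = "death_90d",
                             reference = NULL,
                             roc_test = c("delong", "wald")) {
  roc_test <- match.arg(roc_test)
  if (is.null(data[[outcome]])) {
    stop_hepascore("validation", sprintf("outcome column '%s' missing", outcome))
  }
  y <- as_outcome(data[[outcome]], outcome)
  if (is.null(scores)) {
    candidates <- c("Mortality Risk Score" = "risk_points",
                    "labMELD" = "labmeld",
                    "PS/P-POSSUM" = "ps", "OS/P-POSSUM" = "os",
                    "P-POSSUM mortality %" = "ppossum_pct")
    scores <- candidates[candidates %in% names(data)]
  }
  if (length(scores) == 0L) stop_hepascore("validation", "no score columns selected")
  if (is.null(names(scores)) || any(names(scores) == "")) names(scores) <- scores
  degenerate <- sum(y) == 0L || sum(y) == length(y)

  rocs <- list(); auc_rows <- list()
  for (lab in names(scores)) {
    col <- scores[[lab]]
    if (is.null(data[[col]])) stop_hepascore("schema", sprintf("%s missing", col))
    if (degenerate) {
      auc_rows[[lab]] <- data.frame(score = lab, auc = NA_real_, se = NA_real_,
                                    ci_low = NA_real_, ci_high = NA_real_,
                                    note = "single outcome class; AUC undefined",
                                    stringsAsFactors = FALSE)
      next
    }
    r <- roc_curve(data[[col]], y)
    rocs[[lab]] <- r
    auc_rows[[lab]] <- data.frame(
      score = lab, auc = r$auc, se = r$auc_se,
      ci_low = max(0, r$auc - 1.959964 * r$auc_se),
      ci_high = min(1, r$auc + 1.959964 * r$auc_se),
      note = "", stringsAsFactors = FALSE
    )
  }
  auc_tab <- do.call(rbind, auc_rows); rownames(auc_tab) <- NULL

  reference <- reference %||% names(scores)[1L]
  comp_rows <- list()
  if (!degenerate && length(scores) > 1L) {
    for (lab in setdiff(names(scores), reference)) {
      cmp <- compare_scores(data[[scores[[reference]]]], data[[scores[[lab]]]],
                            y, method = roc_test)
      comp_rows[[lab]] <- data.frame(
        reference = reference, score = lab, auc_ref = cmp$auc_a,
        auc = cmp$auc_b, difference = cmp$difference, se = cmp$se,
        z = cmp$z, p_value = cmp$p_value, method = cmp$method,
        stringsAsFactors = FALSE
      )
    }
  }
  comparisons <- if (length(comp_rows)) {
    out <- do.call(rbind, comp_rows); rownames(out) <- NULL; out
  } else NULL

  table_risk <- NULL
  if ("risk_points" %in% scores || "risk_group" %in% names(data)) {
    grp <- if (!is.null(data$risk_group)) {
      factor(as.character(data$risk_group), levels = risk_groups, ordered = TRUE)
    } else risk_group(data[["risk_points"]])
    table_risk <- stratified_mortality_table(grp, y, reference = "1")
  }
  table_labmeld <- NULL
  if ("labmeld" %in% scores || "labmeld" %in% names(data)) {
    lv <- if (!is.null(data$labmeld_level)) {
      factor(as.character(data$labmeld_level),
             levels = c("6", "7", "8", "9+10", "11-14", ">=15"), ordered = TRUE)
    } else labmeld_level(data[["labmeld"]])
    table_labmeld <- stratified_mortality_table(lv, y, reference = "6")
  }

  group_summary <- NULL
  if (!is.null(table_risk)) {
    grp_df <- data
    grp_df$risk_group <- if (!is.null(data$risk_group)) data$risk_group else risk_group(data[["risk_points"]])
    comp_cols <- intersect(c("labmeld", "ppossum_pct", "ps", "os"), names(data))
    if (length(comp_cols)) {
      group_summary <- group_score_summary(grp_df, "risk_group", comp_cols)
    }
  }

  structure(list(auc = auc_tab, comparisons = comparisons, rocs = rocs,
                 table_risk = table_risk, table_labmeld = table_labmeld,
                 group_summary = group_summary, n = length(y),
                 n_events = sum(y), roc_test = roc_test),
            class = "score_validation")
}

#' @export
print.score_validation <- function(x, ...) {
  cat(sprintf("Score validation: %d patients, %d events (%.1f%%)\n\n",
              x$n, x$n_events, 100 * x$n_events / x$n))
  tab <- x$auc
  tab$auc <- round(tab$auc, 4); tab$se <- round(tab$se, 4)
  tab$ci_low <- round(tab$ci_low, 4); tab$ci_high <- round(tab$ci_high, 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat(sprintf("\nPairwise AUC comparisons vs %s (%s):\n",
                x$comparisons$reference[1L], x$roc_test))
    cmp <- x$comparisons[, c("score", "auc", "difference", "p_value")]
    cmp$auc <- round(cmp$auc, 4); cmp$difference <- round(cmp$difference, 4)
    cmp$p_value <- signif(cmp$p_value, 3)
    print(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname score_validation
#' @param object,x A `"score_validation"` object.
#' @param ... Unused.
#' @export
summary.score_validation <- function(object, ...) {
  print(object)
  if (!is.null(object$table_risk)) {
    cat("\nRisk-score group mortality table:\n")
    print(round_table(object$table_risk), row.names = FALSE)
  }
  if (!is.null(object$table_labmeld)) {
    cat("\nlabMELD level mortality table:\n")
    print(round_table(object$table_labmeld), row.names = FALSE)
  }
  invisible(object)
}

round_table <- function(tab) {
  tab$pct_events <- round(tab$pct_events, 1)
  for (col in c("odds_ratio", "ci_low", "ci_high")) tab[[col]] <- round(tab[[col]], 2)
  tab$p_value <- signif(tab$p_value, 3)
  tab
}

#' @export
plot.score_validation <- function(x, ...) {
  if (length(x$rocs) == 0L) {
    warning("no ROC curves to plot")
    return(invisible(x))
  }
  cols <- grDevices::hcl.colors(max(3L, length(x$rocs)), "Dark 3")
  first <- TRUE
  for (i in seq_along(x$rocs)) {
    plot(x$rocs[[i]], add = !first, col = cols[i], ...)
    first <- FALSE
  }
  graphics::legend("bottomright", legend = names(x$rocs),
                   col = cols[seq_along(x$rocs)], lwd = 2, bty = "n")
  invisible(x)
}
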