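# The eight-component additive mortality risk score for liver resection.
#
# Point awards (preoperative values; inclusive thresholds unless noted):
#   age >= 60 years ....................... 1
#   right trisectionectomy ................ 1
#   INR >= 1.1 ............................ 1
#   GGT >= 60 U/l ......................... 1
#   platelets < 120 /nl (strict) .......... 2
#   creatinine >= 2 mg/dl ................. 3
#   intrahepatic / perihilar CC ........... 1 / 2
#   ASA III / IV .......................... 1 / 5
# Maximum 1+1+1+1+2+3+2+5 = 16 points.

#' Mortality Risk Score points for liver resection
#'
#' Computes the additive preoperative Mortality Risk Score (0--16 points)
#' from eight clinical factors and assigns the corresponding risk group.
#' One point each is awarded for age >= 60 years, right trisectionectomy,
#' INR >= 1.1 and GGT >= 60 U/l; two points for a platelet count
#' < 120/nl; three points for creatinine >= 2 mg/dl; histology scores
#' intrahepatic cholangiocarcinoma 1 and perihilar cholangiocarcinoma 2;
#' ASA III scores 1 and ASA IV scores 5.  All ">=" thresholds are
#' inclusive and the platelet threshold is strict, exactly as defined.
#'
#' Missing values in any scored field are an error (no imputation): a
#' record that cannot be scored must be handled explicitly by the caller
#' (see [score_cohort()], which routes such rows to a rejects table).
#'
#' @param record A list or data.frame with (at least) the fields
#'   `age_years`, `right_trisectionectomy`, `inr`, `ggt_u_per_l`,
#'   `platelets_per_nl`, `creatinine_mg_dl`, `diagnosis` (one of
#'   `"intrahepatic_cc"`, `"perihilar_cc"`, `"other"`) and `asa_class`
#'   (integer 1--4; ASA V is not scored and is rejected).  May contain
#'   one row per patient; all computations are vectorized.
#'
#' @return An object of class `"risk_score"`: a list with elements
#'   `points` (integer vector), `components` (matrix of per-factor
#'   awards; rows sum to `points`), `group` (ordered factor with levels
#'   `1 < 2A < 2B < 3A < 3B < 4`) and `group_description`.
#'
#' @examples
#' rec <- list(age_years = 65, right_trisectionectomy = TRUE, inr = 1.2,
#'             ggt_u_per_l = 100, platelets_per_nl = 150,
#'             creatinine_mg_dl = 1.0, diagnosis = "perihilar_cc",
#'             asa_class = 3)
#' mortality_risk_points(rec)   # 7 points, group 4 (high-risk)
#' @seealso [risk_group()] for the points-to-group mapping.
#' @export
mortality_risk_points <- function(record) {
  rec <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(rec) == 0L) stop_hepascore("schema", "no records to score")
  for (f in risk_score_fields) {
    if (!f %in% names(rec)) stop_hepascore("schema", sprintf("%s missing", f))
    if (anyNA(rec[[f]])) {
      stop_hepascore("schema", sprintf("%s missing (row %d)", f, which(is.na(rec[[f]]))[1L]))
    }
  }
  if (!all(rec$asa_class %in% 1:4)) {
    stop_hepascore("domain", "asa_class must be 1, 2, 3 or 4 (ASA V is not scored)")
  }
  if (!all(rec$diagnosis %in% diagnosis_levels)) {
    stop_hepascore("domain", sprintf(
      "diagnosis must be one of %s", paste(diagnosis_levels, collapse = ", ")
    ))
  }
  check_number(rec$age_years, "age_years", lower = 0)
  check_number(rec$inr, "inr", lower = 0, strict_lower = TRUE)
  check_number(rec$ggt_u_per_l, "ggt_u_per_l", lower = 0)
  check_number(rec$platelets_per_nl, "platelets_per_nl", lower = 0)
  check_number(rec$creatinine_mg_dl, "creatinine_mg_dl", lower = 0, strict_lower = TRUE)
  trisect <- as.logical(rec$right_trisectionectomy)
  if (anyNA(trisect)) stop_hepascore("domain", "right_trisectionectomy must be logical")

  components <- cbind(
    age              = as.integer(rec$age_years >= 60),
    trisectionectomy = as.integer(trisect),
    inr              = as.integer(rec$inr >= 1.1),
    ggt              = as.integer(rec$ggt_u_per_l >= 60),
    platelets        = 2L * as.integer(rec$platelets_per_nl < 120),
    creatinine       = 3L * as.integer(rec$creatinine_mg_dl >= 2),
    diagnosis        = unname(c(intrahepatic_cc = 1L, perihilar_cc = 2L,
                                other = 0L)[rec$diagnosis]),
    asa              = c(0L, 0L, 1L, 5L)[rec$asa_class]
  )
  points <- as.integer(rowSums(components))
  group <- risk_group(points)
  structure(
    list(points = points, components = components, group = group,
         group_description = unname(risk_group_descriptions[as.character(group)])),
    class = "risk_score"
  )
}

#' @export
print.risk_score <- function(x, ...) {
  n <- length(x$points)
  cat(sprintf("Mortality Risk Score (%d record%s)\n", n, if (n == 1L) "" else "s"))
  show <- data.frame(points = x$points, group = x$group,
                     description = x$group_description)
  if (n <= 10L) {
    print(cbind(as.data.frame(x$components), show), ...)
  } else {
    cat("points: "); print(summary(x$points))
    cat("groups:\n"); print(table(x$group))
  }
  invisible(x)
}

#' Risk group from Mortality Risk Score points
#'
#' Maps score points to the six risk groups: 0--1 points -> group 1
#' (very low-risk), 2 -> 2A, 3 -> 2B (low-risk), 4 -> 3A, 5 -> 3B
#' (medium-risk), >= 6 -> 4 (high-risk).
#'
#' @param points Integer vector of score points, 0 to 16.
#' @return Ordered factor with levels `1 < 2A < 2B < 3A < 3B < 4`.
#' @examples
#' risk_group(c(0, 2, 5, 16))
#' @export
risk_group <- function(points) {
  check_number(points, "points", lower = 0, upper = 16, integer = TRUE)
  g <- ifelse(points <= 1, "1",
       ifelse(points == 2, "2A",
       ifelse(points == 3, "2B",
       ifelse(points == 4, "3A",
       ifelse(points == 5, "3B", "4")))))
  factor(g, levels = risk_groups, ordered = TRUE)
}

#' Coarse description of a risk group
#'
#' @param group Risk group labels (`"1"`, `"2A"`, ..., `"4"`) or the
#'   factor returned by [risk_group()].
#' @return Character vector: `"very low-risk"`, `"low-risk"`,
#'   `"medium-risk"` or `"high-risk"`.
#' @export
risk_group_description <- function(group) {
  group <- as.character(group)
  if (!all(group %in% risk_groups)) {
    stop_hepascore("domain", "unknown risk group label")
  }
  unname(risk_group_descriptions[group])
}
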