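# File-based pipeline: CSV schema, batch scoring with a rejects table,
# and the validation report writer.  All internal computation is at full
# precision; rounding happens only when report tables are rendered.

core_columns <- c(
  "age_years", "sex", "asa_class", "diagnosis", "right_trisectionectomy",
  "inr", "ggt_u_per_l", "platelets_per_nl", "creatinine_mg_dl",
  "bilirubin_mg_dl", "on_dialysis"
)
possum_columns <- c(paste0("ps_", possum_phys_items),
                    paste0("os_", possum_oper_items))
derived_columns <- c("risk_points", "risk_group", "labmeld", "labmeld_level",
                     "ps", "os", "ppossum_pct")
known_columns <- c("id", core_columns, possum_columns, "death_90d",
                   derived_columns)

#' Read a cohort CSV
#'
#' Reads a patient-level cohort in the package's CSV schema (UTF-8,
#' comma-separated, `.` decimal; one row per patient; column names as in
#' the data dictionary of [generate_cohort()]).  Unknown columns and
#' empty files are schema errors; `death_90d` and the POSSUM item
#' columns are optional (scoring does not require an outcome).
#'
#' @param path Path to the CSV file.
#' @param require_outcome Require a `death_90d` column (as
#'   [cmd_validate()] does).
#' @return Data frame.
#' @export
read_cohort_csv <- function(path, require_outcome = FALSE) {
  if (!file.exists(path)) stop_hepascore("schema", sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_hepascore("schema",
                   sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop_hepascore("schema", sprintf("empty cohort file: %s", path))
  }
  unknown <- setdiff(names(df), known_columns)
  if (length(unknown)) {
    stop_hepascore("schema", sprintf("unknown column(s): %s",
                                     paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(core_columns, names(df))
  if (length(missing)) {
    stop_hepascore("schema", sprintf("missing required column(s): %s",
                                     paste(missing, collapse = ", ")))
  }
  if (require_outcome && !"death_90d" %in% names(df)) {
    stop_hepascore("validation", "no outcome column death_90d in input")
  }
  df
}

#' Write a cohort CSV
#'
#' Writes the standard cohort schema.  Numeric columns are serialized
#' with 17 significant digits so that a write/read round trip is
#' lossless for double precision values.
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  out <- data
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- sub("^NA$", "", sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Score a cohort
#'
#' Appends the score columns (`risk_points`, `risk_group`, `labmeld`,
#' `ps`, `os`, `ppossum_pct`) to a cohort.  Rows that cannot be scored
#' -- a missing or invalid value in any field required by a selected
#' score -- are routed to a rejects table with a reason naming the
#' offending field; they are never silently dropped or imputed.
#'
#' @param data Cohort data frame (see [read_cohort_csv()]).
#' @param scores Subset of `c("risk_score", "labmeld", "ppossum")` to
#'   compute.
#' @param force_major Floor the operative-severity POSSUM grade at
#'   "major" (see [possum_operative_score()]).
#' @return List with `scored` (the scorable rows with appended columns)
#'   and `rejects` (data frame `row`, `reason`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 50, seed = 7))
#' res <- score_cohort(coh)
#' head(res$scored[, c("risk_points", "risk_group", "labmeld", "ppossum_pct")])
#' @export
score_cohort <- function(data, scores = c("risk_score", "labmeld", "ppossum"),
                         force_major = TRUE) {
  scores <- match.arg(scores, several.ok = TRUE)
  if (nrow(data) == 0L) stop_hepascore("schema", "no records to score")
  n <- nrow(data)
  reason <- character(n)

  need <- character(0)
  if ("risk_score" %in% scores) need <- union(need, risk_score_fields)
  if ("labmeld" %in% scores) {
    need <- union(need, c("creatinine_mg_dl", "bilirubin_mg_dl", "inr", "on_dialysis"))
  }
  if ("ppossum" %in% scores) need <- union(need, possum_columns)

  for (f in need) {
    if (!f %in% names(data)) stop_hepascore("schema", sprintf("%s missing", f))
    bad <- is.na(data[[f]]) & reason == ""
    reason[bad] <- sprintf("%s missing", f)
  }
  # value-level checks, applied only to rows not already rejected
  flag <- function(bad, msg) reason[bad & reason == ""] <<- msg
  if ("risk_score" %in% scores) {
    flag(!data$asa_class %in% 1:4, "asa_class out of range")
    flag(!data$diagnosis %in% diagnosis_levels, "diagnosis invalid")
    flag(data$age_years < 0, "age_years invalid")
    flag(data$inr <= 0, "inr invalid")
    flag(data$platelets_per_nl < 0, "platelets_per_nl invalid")
    flag(data$creatinine_mg_dl <= 0, "creatinine_mg_dl invalid")
    flag(data$ggt_u_per_l < 0, "ggt_u_per_l invalid")
  }
  if ("labmeld" %in% scores) {
    flag(data$creatinine_mg_dl <= 0, "creatinine_mg_dl invalid")
    flag(data$bilirubin_mg_dl <= 0, "bilirubin_mg_dl invalid")
    flag(data$inr <= 0, "inr invalid")
  }
  if ("ppossum" %in% scores) {
    for (f in possum_columns) flag(!data[[f]] %in% possum_grades, sprintf("%s invalid grade", f))
  }

  ok <- reason == ""
  scored <- data[ok, , drop = FALSE]
  if (any(ok)) {
    if ("risk_score" %in% scores) {
      rs <- mortality_risk_points(scored)
      scored$risk_points <- rs$points
      scored$risk_group <- as.character(rs$group)
    }
    if ("labmeld" %in% scores) {
      scored$labmeld <- labmeld(scored$creatinine_mg_dl, scored$bilirubin_mg_dl,
                                scored$inr, scored$on_dialysis)
    }
    if ("ppossum" %in% scores) {
      ps_mat <- as.matrix(scored[, paste0("ps_", possum_phys_items)])
      os_mat <- as.matrix(scored[, paste0("os_", possum_oper_items)])
      if (force_major) os_mat[, "os_severity"] <- pmax(os_mat[, "os_severity"], 4L)
      scored$ps <- as.integer(rowSums(ps_mat))
      scored$os <- as.integer(rowSums(os_mat))
      scored$ppossum_pct <- 100 * ppossum_mortality(scored$ps, scored$os)
    }
  }
  rejects <- data.frame(row = which(!ok), reason = reason[!ok],
                        stringsAsFactors = FALSE)
  list(scored = scored, rejects = rejects)
}

write_manifest <- function(outdir, step, extra = list()) {
  manifest <- c(list(
    step = step,
    package = "hepascore",
    version = as.character(utils::packageVersion("hepascore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  path <- file.path(outdir, paste0(step, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

spec_hash <- function(spec) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- lapply(unclass(spec), function(x) if (is.list(x)) x else as.vector(x))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort (or a deterministic reconstruction of a
#' published stratum table) and writes it as CSV together with a JSON
#' manifest recording the seed, a hash of the specification, and file
#' checksums, sufficient to reproduce the run.
#'
#' @param outdir Output directory (created if needed).
#' @param spec A [cohort_spec()]; ignored when `table` is given.
#' @param table `NULL`, or `"risk_score"`/`"labmeld"` to emit a
#'   [reconstruct_printed_cohort()] instead of a random cohort.
#' @param file File name within `outdir`.
#' @return Path of the written CSV, invisibly.
#' @export
cmd_simulate <- function(outdir, spec = cohort_spec(), table = NULL,
                         file = "cohort.csv") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(table)) {
    cohort <- reconstruct_printed_cohort(table)
    extra <- list(table = table, n = nrow(cohort))
  } else {
    if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, as.list(spec))
    cohort <- generate_cohort(spec)
    extra <- list(n = spec$n, seed = spec$seed, spec_md5 = spec_hash(spec))
  }
  path <- file.path(outdir, file)
  write_cohort_csv(cohort, path)
  extra$file <- file
  extra$file_md5 <- unname(tools::md5sum(path))
  write_manifest(outdir, "simulate", extra)
  invisible(path)
}

#' Score a cohort file
#'
#' Reads a cohort CSV, applies [score_cohort()], and writes
#' `scored.csv`, `rejects.csv` and a manifest to `outdir`.
#'
#' @param input Input cohort CSV path.
#' @param outdir Output directory.
#' @inheritParams score_cohort
#' @return Path of the scored CSV, invisibly.
#' @export
cmd_score <- function(input, outdir,
                      scores = c("risk_score", "labmeld", "ppossum"),
                      force_major = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data <- read_cohort_csv(input)
  res <- score_cohort(data, scores = scores, force_major = force_major)
  path <- file.path(outdir, "scored.csv")
  write_cohort_csv(res$scored, path)
  utils::write.csv(res$rejects, file.path(outdir, "rejects.csv"), row.names = FALSE)
  write_manifest(outdir, "score", list(
    input = input, n_in = nrow(data), n_scored = nrow(res$scored),
    n_rejected = nrow(res$rejects), scores = scores,
    file_md5 = unname(tools::md5sum(path))
  ))
  invisible(path)
}

#' Validate scored cohort file and write report tables
#'
#' Reads a scored cohort CSV (outcome required) and writes the
#' validation report: `table2.csv` (risk-score strata), `table3.csv`
#' (labMELD strata), `table4.csv` (AUC per score with 95% CI and
#' pairwise comparisons), `table5.csv` (per-risk-group distribution of
#' the comparator scores), one `roc_<score>.csv` of operating points per
#' score, and a JSON run manifest.  Percentages in the stratum tables
#' are rendered with one decimal; all other columns keep full precision.
#'
#' @param input Scored cohort CSV (e.g. from [cmd_score()]).
#' @param outdir Output directory.
#' @param roc_test `"delong"` or `"wald"` for ROC comparisons.
#' @return The [score_validation()] object, invisibly.
#' @export
cmd_validate <- function(input, outdir, roc_test = c("delong", "wald")) {
  roc_test <- match.arg(roc_test)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data <- read_cohort_csv(input, require_outcome = TRUE)
  val <- score_validation(data, roc_test = roc_test)

  render_strata <- function(tab) {
    if (is.null(tab)) return(NULL)
    tab$pct_events <- sprintf("%.1f", tab$pct_events)
    tab
  }
  if (!is.null(val$table_risk)) {
    utils::write.csv(render_strata(val$table_risk),
                     file.path(outdir, "table2.csv"), row.names = FALSE)
  }
  if (!is.null(val$table_labmeld)) {
    utils::write.csv(render_strata(val$table_labmeld),
                     file.path(outdir, "table3.csv"), row.names = FALSE)
  }
  tab4 <- val$auc
  if (!is.null(val$comparisons)) {
    m <- match(tab4$score, val$comparisons$score)
    tab4$p_vs_reference <- val$comparisons$p_value[m]
  }
  utils::write.csv(tab4, file.path(outdir, "table4.csv"), row.names = FALSE)
  if (!is.null(val$group_summary)) {
    utils::write.csv(val$group_summary, file.path(outdir, "table5.csv"),
                     row.names = FALSE)
  }
  for (lab in names(val$rocs)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", tolower(lab))
    utils::write.csv(val$rocs[[lab]]$points,
                     file.path(outdir, sprintf("roc_%s.csv", safe)),
                     row.names = FALSE)
  }
  write_manifest(outdir, "validate", list(
    input = input, n = val$n, n_events = val$n_events, roc_test = roc_test,
    scores = val$auc$score
  ))
  invisible(val)
}
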