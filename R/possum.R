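# P-POSSUM: Portsmouth modification of the Physiological and Operative
# Severity Score for the enUmeration of Mortality and morbidity.
#
# Twelve physiological items and six operative items are each graded
# 1/2/4/8 according to the original POSSUM banding tables (Copeland et
# al. 1991, shipped as a plain-text data file in inst/extdata so the
# transcription is auditable and replaceable).  The physiological score
# PS is the sum of the 12 physiological grades (12..96), the operative
# severity score OS the sum of the 6 operative grades (6..48), and the
# Portsmouth in-patient mortality equation is
#   ln(R / (1 - R)) = -9.065 + 0.1692 * PS + 0.1550 * OS.

.hepascore_cache <- new.env(parent = emptyenv())

#' POSSUM item banding table
#'
#' Returns the banding table used to grade raw POSSUM items, as shipped
#' in `inst/extdata/possum_bands.csv`.  Numeric items carry inclusive
#' `low`/`high` bounds at the table's printed resolution (`res`);
#' categorical items carry named `level`s.  Each band maps to a grade in
#' \{1, 2, 4, 8\}.
#'
#' @return Data frame with columns `domain` (`"phys"`/`"oper"`), `item`,
#'   `kind` (`"numeric"`/`"categorical"`), `grade`, `low`, `high`,
#'   `level`, `res`.
#' @export
possum_bands <- function() {
  if (is.null(.hepascore_cache$bands)) {
    path <- system.file("extdata", "possum_bands.csv", package = "hepascore")
    if (path == "") path <- file.path("inst", "extdata", "possum_bands.csv")
    .hepascore_cache$bands <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .hepascore_cache$bands
}

# Grade one raw value against the band table for `item`.
grade_one <- function(item, value, domain) {
  tab <- possum_bands()
  tab <- tab[tab$domain == domain & tab$item == item, , drop = FALSE]
  if (nrow(tab) == 0L) stop_hepascore("schema", sprintf("unknown POSSUM item: %s", item))
  if (tab$kind[1L] == "categorical") {
    hit <- match(as.character(value), tab$level)
    if (is.na(hit)) {
      stop_hepascore("domain", sprintf(
        "%s: unknown level '%s' (expected one of %s)",
        item, value, paste(tab$level, collapse = ", ")
      ))
    }
    return(as.integer(tab$grade[hit]))
  }
  if (!is.numeric(value) || is.na(value) || !is.finite(value)) {
    stop_hepascore("domain", sprintf("%s: raw measurement must be a finite number", item))
  }
  # snap to the table's printed resolution, then band lookup
  res <- tab$res[1L]
  v <- round(value / res) * res
  hit <- which(v >= tab$low - 1e-9 & v <= tab$high + 1e-9)
  if (length(hit) == 0L) {
    stop_hepascore("domain", sprintf("%s: value %s outside all bands", item, format(value)))
  }
  as.integer(tab$grade[hit[1L]])
}

#' Grade raw physiological measurements into POSSUM items
#'
#' Maps twelve raw physiological measurements to their POSSUM grades
#' (1/2/4/8) using the original banding tables.  Every item must be
#' provided: missing items are an error, never imputed (callers holding
#' already-graded items can skip this step entirely and pass grades to
#' [possum_physiological_score()] directly).
#'
#' @param raw Named list (or vector) with entries `age`, `cardiac`,
#'   `respiratory`, `sbp` (systolic blood pressure, mmHg), `pulse`
#'   (beats/min), `gcs` (Glasgow Coma Scale), `hb` (haemoglobin, g/dl),
#'   `wcc` (white cell count, 10^9/l), `urea` (mmol/l), `sodium`
#'   (mmol/l), `potassium` (mmol/l) and `ecg`.  `cardiac`,
#'   `respiratory` and `ecg` are categorical levels (see
#'   [possum_bands()]); the rest are numeric measurements.
#'
#' @return Named integer vector of 12 grades, in canonical item order.
#' @examples
#' grade_physiology(list(age = 45, cardiac = "no_failure",
#'   respiratory = "no_dyspnoea", sbp = 120, pulse = 70, gcs = 15,
#'   hb = 14, wcc = 8, urea = 5, sodium = 140, potassium = 4.2,
#'   ecg = "normal"))
#' @export
grade_physiology <- function(raw) {
  raw <- as.list(raw)
  miss <- setdiff(possum_phys_items, names(raw))
  if (length(miss)) {
    stop_hepascore("schema", sprintf("missing raw physiological item: %s", miss[1L]))
  }
  vapply(possum_phys_items, function(it) grade_one(it, raw[[it]], "phys"),
         integer(1))
}

#' Grade raw operative findings into POSSUM items
#'
#' Operative counterpart of [grade_physiology()]: maps the six operative
#' items to grades 1/2/4/8.
#'
#' @param raw Named list with entries `severity` (`"minor"`,
#'   `"moderate"`, `"major"`, `"major_plus"`), `multiple` (`"one"`,
#'   `"two"`, `"more_than_two"` procedures), `blood_loss` (ml, numeric),
#'   `soiling`, `malignancy` and `mode` (see [possum_bands()] for
#'   levels).
#' @return Named integer vector of 6 grades.
#' @export
grade_operative <- function(raw) {
  raw <- as.list(raw)
  miss <- setdiff(possum_oper_items, names(raw))
  if (length(miss)) {
    stop_hepascore("schema", sprintf("missing raw operative item: %s", miss[1L]))
  }
  vapply(possum_oper_items, function(it) grade_one(it, raw[[it]], "oper"),
         integer(1))
}

check_grades <- function(items, n_expected, what) {
  if (length(items) != n_expected) {
    stop_hepascore("domain", sprintf("%s requires exactly %d item grades, got %d",
                                     what, n_expected, length(items)))
  }
  if (!is.numeric(items) || anyNA(items) || !all(items %in% possum_grades)) {
    stop_hepascore("domain", sprintf("%s item grades must all be in {1, 2, 4, 8}", what))
  }
  as.integer(items)
}

#' POSSUM physiological score
#'
#' Sum of the 12 physiological item grades; ranges 12 (all normal) to 96.
#'
#' @param items Numeric vector of 12 grades, each in \{1, 2, 4, 8\}
#'   (order is irrelevant for the sum).
#' @return Integer PS in 12--96.
#' @export
possum_physiological_score <- function(items) {
  sum(check_grades(items, 12L, "physiological score"))
}

#' POSSUM operative severity score
#'
#' Sum of the 6 operative item grades; ranges 6 to 48.  For elective
#' hepatectomy cohorts the operative severity item is conventionally
#' floored at "major": with `force_major = TRUE` (default) the severity
#' grade becomes `max(grade, 4)`, so a "major+" (grade 8) case is never
#' downgraded.
#'
#' @param items Numeric vector of 6 grades in \{1, 2, 4, 8\}.  If named,
#'   the severity item is identified by the name `"severity"`; otherwise
#'   it is taken to be the first element (canonical order severity,
#'   multiple, blood_loss, soiling, malignancy, mode).
#' @param force_major Floor the operative-severity grade at 4 ("major").
#' @return Integer OS in 6--48.
#' @export
possum_operative_score <- function(items, force_major = TRUE) {
  items <- check_grades(items, 6L, "operative score")
  if (force_major) {
    i <- if (!is.null(names(items)) && "severity" %in% names(items)) {
      match("severity", names(items))
    } else 1L
    items[i] <- max(items[i], 4L)
  }
  sum(items)
}

#' P-POSSUM predicted mortality
#'
#' Portsmouth POSSUM in-patient mortality risk from the physiological
#' score (PS) and operative severity score (OS):
#' \deqn{\ln(R/(1-R)) = -9.065 + 0.1692 \cdot PS + 0.1550 \cdot OS.}
#' R is strictly increasing in both scores.
#'
#' @param ps Physiological score, integer in 12--96.
#' @param os Operative severity score, integer in 6--48.
#' @return Predicted mortality risk R in (0, 1); vectorized.
#' @examples
#' ppossum_mortality(12, 6)    # healthiest possible profile, ~0.2%
#' ppossum_mortality(16, 17)   # ~2.4%
#' @export
ppossum_mortality <- function(ps, os) {
  check_number(ps, "ps", lower = 12, upper = 96, integer = TRUE)
  check_number(os, "os", lower = 6, upper = 48, integer = TRUE)
  inv_logit(-9.065 + 0.1692 * ps + 0.1550 * os)
}
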