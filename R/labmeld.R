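#' Laboratory MELD score
#'
#' Computes the laboratory Model for End-stage Liver Disease score from
#' serum creatinine, serum bilirubin and INR:
#'
#' \deqn{labMELD = 10 \times (0.957 \ln(creatinine) + 0.378 \ln(bilirubin)
#'   + 1.120 \ln(INR) + 0.643)}
#'
#' with the usual conventions: creatinine is capped at 4 mg/dl and set to
#' 4 mg/dl for patients dialysed at least twice in the preceding week;
#' every component is floored at 1 before taking logarithms (so no
#' component contributes negatively); the result is rounded to the
#' nearest integer (halves up) and clamped to the attainable range
#' [6, 40].
#'
#' @param creatinine_mg_dl Serum creatinine in mg/dl (> 0).
#' @param bilirubin_mg_dl Serum total bilirubin in mg/dl (> 0).
#' @param inr International normalized ratio (> 0).
#' @param on_dialysis Logical; dialysis at least twice in the previous
#'   week forces the creatinine component to 4 mg/dl.
#' @param round Return the rounded, clamped integer score (default).
#'   `round = FALSE` returns the raw formula value after the cap/floor
#'   rules but before rounding and clamping, which is useful for
#'   checking the arithmetic against an independent evaluation.
#'
#' @return Integer score in 6--40 (or the unrounded real value when
#'   `round = FALSE`).  Vectorized over all four inputs.
#'
#' @examples
#' labmeld(1.0, 1.0, 1.0)          # 6, the attainable minimum
#' labmeld(6.0, 2.0, 1.5)          # 27 (creatinine capped at 4)
#' labmeld(1.0, 1.0, 1.0, on_dialysis = TRUE)  # 20
#' @export
labmeld <- function(creatinine_mg_dl, bilirubin_mg_dl, inr,
                    on_dialysis = FALSE, round = TRUE) {
  check_number(creatinine_mg_dl, "creatinine_mg_dl", lower = 0, strict_lower = TRUE)
  check_number(bilirubin_mg_dl, "bilirubin_mg_dl", lower = 0, strict_lower = TRUE)
  check_number(inr, "inr", lower = 0, strict_lower = TRUE)
  on_dialysis <- as.logical(on_dialysis)
  if (anyNA(on_dialysis)) stop_hepascore("domain", "on_dialysis must be logical")

  n <- max(length(creatinine_mg_dl), length(bilirubin_mg_dl),
           length(inr), length(on_dialysis))
  cre <- rep_len(creatinine_mg_dl, n)
  bil <- rep_len(bilirubin_mg_dl, n)
  rin <- rep_len(inr, n)
  dia <- rep_len(on_dialysis, n)

  cre <- ifelse(dia, 4, pmin(cre, 4))  # dialysis override, then 4 mg/dl cap
  cre <- pmax(cre, 1)                  # component floors
  bil <- pmax(bil, 1)
  rin <- pmax(rin, 1)

  value <- 10 * (0.957 * log(cre) + 0.378 * log(bil) + 1.120 * log(rin) + 0.643)
  if (!round) return(value)
  as.integer(pmin(pmax(round_half_up(value), 6), 40))
}
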