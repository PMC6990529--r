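# Shared internal helpers.  Error conditions are classed so that callers
# (and the command-line wrapper) can distinguish schema problems, invalid
# clinical values, and statistical degeneracies.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_hepascore <- function(type, msg) {
  cls <- switch(type,
    schema     = "hepascore_schema_error",
    validation = "hepascore_validation_error",
    # domain errors (clinically impossible values) are a kind of validation error
    domain     = c("hepascore_domain_error", "hepascore_validation_error"),
    stats      = "hepascore_stats_error",
    stop("unknown error type: ", type)
  )
  cond <- structure(
    class = c(cls, "hepascore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Numerically stable inverse logit; avoids overflow of exp() for large |eta|.
inv_logit <- function(eta) {
  out <- numeric(length(eta))
  pos <- !is.na(eta) & eta >= 0
  out[pos] <- 1 / (1 + exp(-eta[pos]))
  out[!pos] <- exp(eta[!pos]) / (1 + exp(eta[!pos]))
  out[is.na(eta)] <- NA_real_
  out
}

# Round halves away from zero for positive x (UNOS-style integer scores).
round_half_up <- function(x) floor(x + 0.5)

# Coerce an outcome vector to 0/1 integer.
as_outcome <- function(y, what = "outcome") {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1))) {
    stop_hepascore("validation", sprintf("%s must be binary (0/1, logical) with no missing values", what))
  }
  as.integer(y)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_hepascore("domain", sprintf("%s must be finite and non-missing", name))
  }
  bad <- if (strict_lower) x <= lower else x < lower
  if (any(bad | x > upper)) {
    stop_hepascore("domain", sprintf(
      "%s out of range (%s%s, %s]", name,
      if (strict_lower) "(" else "[", lower, upper
    ))
  }
  if (integer && any(x != round(x))) {
    stop_hepascore("domain", sprintf("%s must be integer-valued", name))
  }
  invisible(x)
}
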