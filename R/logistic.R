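# Maximum-likelihood logistic regression by Newton-Raphson, written out
# so that the Wald statistics behind the validation tables are fully
# reproducible.  stats::glm serves as the independent oracle in the test
# suite.

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression fitted by Newton-Raphson on
#' the binomial log-likelihood, with step-halving if an update does not
#' improve the likelihood.  Convergence is declared when the largest
#' coefficient update falls below `tol` (default 1e-8) within
#' `max_iter` iterations.  The covariance matrix is the inverse of the
#' observed information at the optimum.
#'
#' Complete separation is detected (coefficients diverging beyond +/-30
#' on the logit scale with fitted probabilities collapsing to 0/1) and
#' flagged via `$separated` rather than raised as an error, so callers
#' can report such strata gracefully.  A rank-deficient design matrix is
#' an error.
#'
#' @param formula Model formula; the response must be binary (logical,
#'   0/1, or a two-level factor with the second level as the event).
#' @param data Data frame in which to evaluate the formula.
#' @param tol Convergence tolerance on the coefficient update.
#' @param max_iter Maximum Newton iterations.
#'
#' @return Object of class `"score_logit"` with components
#'   `coefficients`, `vcov`, `fitted.values`, `linear.predictors`,
#'   `loglik`, `deviance`, `iter`, `converged`, `separated`, `y`,
#'   `terms`, `call`.  Methods: `print`, `summary`, `coef`, `vcov`,
#'   `predict`, `residuals`, `logLik`, `nobs`, `simulate`.
#'
#' @examples
#' d <- data.frame(x = c(0, 0, 0, 1, 1, 1, 1), y = c(0, 0, 1, 0, 1, 1, 1))
#' fit <- fit_logistic(y ~ x, d)
#' exp(coef(fit)["x"])   # odds ratio of the 2x2 table
#' @export
fit_logistic <- function(formula, data, tol = 1e-8, max_iter = 100L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  mt <- attr(mf, "terms")
  y <- as_outcome(stats::model.response(mf), "response")
  X <- stats::model.matrix(mt, mf)
  n <- length(y); p <- ncol(X)

  if (sum(y) == 0L || sum(y) == n) {
    stop_hepascore("stats", "outcome is constant (need at least one event and one non-event)")
  }
  if (qr(X)$rank < p) {
    stop_hepascore("stats", "rank-deficient design matrix (collinear columns)")
  }

  beta <- numeric(p)
  loglik <- function(eta) sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  ll <- loglik(drop(X %*% beta))
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) { separated <- TRUE; break }
    # step-halving safeguard
    step <- 1
    repeat {
      cand <- beta + step * drop(delta)
      ll_new <- loglik(drop(X %*% cand))
      if (ll_new >= ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    beta <- cand
    ll <- ll_new
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 30) { separated <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- inv_logit(eta)
  if (!separated && any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(beta)) > 15) {
    separated <- TRUE
  }
  info <- crossprod(X, X * (mu * (1 - mu)))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(
    coefficients = beta, vcov = vc,
    fitted.values = mu, linear.predictors = eta,
    loglik = ll, deviance = -2 * ll, iter = iter,
    converged = converged, separated = separated,
    y = y, terms = mt, xlevels = stats::.getXlevels(mt, mf),
    call = cl, n = n
  ), class = "score_logit")
}

#' @export
print.score_logit <- function(x, ...) {
  cat("Logistic regression (Newton-Raphson ML)\n")
  cat("Call: "); print(x$call)
  cat("\nCoefficients:\n"); print(round(x$coefficients, 6))
  if (x$separated) cat("\nWarning: complete or quasi-complete separation detected\n")
  else if (!x$converged) cat("\nWarning: did not converge\n")
  invisible(x)
}

#' @export
coef.score_logit <- function(object, ...) object$coefficients

#' @export
vcov.score_logit <- function(object, ...) object$vcov

#' @export
logLik.score_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.score_logit <- function(object, ...) object$n

#' @rdname fit_logistic
#' @param object A fitted `"score_logit"` model.
#' @param ... Unused.
#' @export
summary.score_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(call = object$call, coefficients = tab,
                 deviance = object$deviance, iter = object$iter,
                 converged = object$converged, separated = object$separated),
            class = "summary.score_logit")
}

#' @export
print.summary.score_logit <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nResidual deviance: %.4f on %d Newton iterations%s\n",
              x$deviance, x$iter,
              if (x$separated) " (separation detected)" else ""))
  invisible(x)
}

#' @export
predict.score_logit <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") inv_logit(eta) else eta
}

#' @export
residuals.score_logit <- function(object,
                                  type = c("deviance", "pearson", "response"),
                                  ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = {
      d <- -2 * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
      sign(y - mu) * sqrt(pmax(d, 0))
    }
  )
}

#' @export
simulate.score_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, stats::rbinom(object$n, 1L, object$fitted.values)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
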