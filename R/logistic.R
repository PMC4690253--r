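#' Construct a logistic model from known coefficients
#'
#' Builds a \code{logisticModel} object directly from an intercept and named
#' coefficients, e.g. to apply a published model to new subjects.
#'
#' @param intercept intercept on the log-odds scale.
#' @param coefficients named numeric vector of feature coefficients.
#' @param se optional named vector of Wald standard errors.
#' @return object of class \code{logisticModel}.
#' @examples
#' logisticModel(-7.00, c(maxT2 = 0.03, madSD = 20.34))
#' @export
logisticModel <- function(intercept, coefficients, se = NULL) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("'coefficients' must be a named vector")
  structure(list(intercept = intercept, coefficients = coefficients,
                 se = se, oddsRatio = exp(coefficients),
                 ci = if (!is.null(se))
                   cbind(lower = exp(coefficients - 1.96 * se),
                         upper = exp(coefficients + 1.96 * se)),
                 converged = TRUE, separation = FALSE),
            class = "logisticModel")
}

#' Reference two-feature logistic model for ACM detection
#'
#' The multiple logistic regression model reported for the GraSE T2-mapping
#' cohort, with madSD and maxT2 as the independent predictors of acute
#' myocarditis: intercept -7.00, maxT2 coefficient 0.03 per ms, madSD
#' coefficient 20.34.
#'
#' @return a \code{\link{logisticModel}}.
#' @export
referenceLogisticModel <- function() {
  logisticModel(-7.00, c(maxT2 = 0.03, madSD = 20.34))
}

#' Fit a binary logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (\code{stats::glm}, binomial family) with Wald standard errors from the
#' observed information, odds ratios with 95\% CIs, and explicit detection
#' of complete separation (divergent coefficients are flagged rather than
#' returned silently).
#'
#' @param X data.frame or matrix of numeric features.
#' @param y binary labels: logical, 0/1 numeric, or a factor/character where
#'   \code{positiveClass} codes the disease class.
#' @param positiveClass class of \code{y} treated as 1 (default "ACM").
#' @return a \code{logisticModel} with \code{converged} and
#'   \code{separation} flags; the underlying \code{glm} fit is attached as
#'   \code{$fit}.
#' @export
fitLogistic <- function(X, y, positiveClass = "ACM") {
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, TRUE))) stop("features must be numeric")
  y01 <- if (is.logical(y)) as.integer(y)
  else if (is.numeric(y)) as.integer(y != 0)
  else as.integer(as.character(y) == positiveClass)
  if (length(unique(y01)) != 2L) stop("'y' must contain both classes")
  if (nrow(X) <= ncol(X) + 1L) stop("need n > p + 1 observations")
  if (any(vapply(X, function(v) var(v) == 0, TRUE)))
    stop("constant feature column")
  dat <- cbind(X, .y = y01)
  warnSep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        warnSep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separation <- warnSep && any(abs(cf[-1]) > 50 / apply(as.matrix(X), 2, sd))
  m <- logisticModel(unname(cf[1]), cf[-1], se = se[-1])
  m$converged <- fit$converged && !separation
  m$separation <- separation
  m$fit <- fit
  m
}

#' @export
print.logisticModel <- function(x, ...) {
  cat("Logistic model (log-odds scale)\n")
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  for (f in names(x$coefficients))
    cat(sprintf("  %-10s B = %8.4g  OR = %.3g%s\n", f, x$coefficients[f],
                x$oddsRatio[f],
                if (!is.null(x$ci))
                  sprintf("  [%.3g, %.3g]", x$ci[f, 1], x$ci[f, 2]) else ""))
  if (isTRUE(x$separation)) cat("  WARNING: complete separation detected\n")
  invisible(x)
}

#' Predicted disease probability from a logistic model
#'
#' @param model a \code{\link{logisticModel}}.
#' @param newdata data.frame containing the model's feature columns.
#' @return numeric vector of probabilities \eqn{1/(1 + e^{-\eta})}.
#' @export
predictLogistic <- function(model, newdata) {
  stopifnot(inherits(model, "logisticModel"))
  miss <- setdiff(names(model$coefficients), names(newdata))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  eta <- model$intercept
  for (f in names(model$coefficients))
    eta <- eta + model$coefficients[[f]] * newdata[[f]]
  plogis(eta)
}

#' Multiplicative odds change for a feature increment
#'
#' The factor by which the odds p(disease)/p(healthy) change when
#' \code{feature} increases by \code{delta}: \eqn{\exp(B \cdot \delta)}.
#' With the reference model, a 0.1 increase in madSD multiplies the odds by
#' exp(20.34 * 0.1) = 7.64 and a 1 ms increase in maxT2 by exp(0.03) = 1.03.
#'
#' @param model a \code{\link{logisticModel}}.
#' @param feature coefficient name.
#' @param delta increment of the feature.
#' @return scalar odds factor.
#' @examples
#' oddsFactor(referenceLogisticModel(), "madSD", 0.1)
#' @export
oddsFactor <- function(model, feature, delta) {
  stopifnot(inherits(model, "logisticModel"))
  if (!feature %in% names(model$coefficients))
    stop("unknown feature '", feature, "'")
  exp(model$coefficients[[feature]] * delta)
}
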