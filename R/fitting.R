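#' Log-linear least-squares T2 fit for one pixel
#'
#' Ordinary least squares of \code{log(magnitude)} on echo time: the slope
#' gives \code{T2 = -1/slope} and the intercept \code{A = exp(intercept)}.
#' Fast and exact on noiseless data, but biased upward at low SNR where the
#' Rician noise floor lifts late-echo magnitudes; it also serves as the
#' initialiser for \code{\link{fitRicianMLE}}.
#'
#' @param magnitudes numeric vector of echo magnitudes (> 0 required for the
#'   log; non-positive input yields a flagged failure, not an error).
#' @param echoTimes strictly increasing echo times in ms.
#' @return list with \code{T2} (ms), \code{A}, and \code{converged}
#'   (FALSE for non-positive magnitudes or a non-negative slope, i.e.
#'   non-decaying signal).
#' @examples
#' fitLogLinear(c(100, 36.788), c(15, 76.6))   # T2 ~ 61.6 ms
#' @export
fitLogLinear <- function(magnitudes, echoTimes) {
  if (length(magnitudes) != length(echoTimes))
    stop("'magnitudes' and 'echoTimes' must have equal length")
  if (any(diff(echoTimes) <= 0)) stop("'echoTimes' must be strictly increasing")
  if (any(magnitudes <= 0) || any(!is.finite(magnitudes)))
    return(list(T2 = NA_real_, A = NA_real_, converged = FALSE))
  y <- log(magnitudes)
  te <- echoTimes
  sxx <- sum((te - mean(te))^2)
  slope <- sum((te - mean(te)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(te)
  if (slope >= -1e-12)  # non-decaying: infinite or negative T2
    return(list(T2 = NA_real_, A = exp(intercept), converged = FALSE))
  list(T2 = -1 / slope, A = exp(intercept), converged = TRUE)
}

# Vectorised log-linear fit: M is an n_pixels x n_echoes matrix, all > 0
# assumed pre-screened. Returns matrix with columns T2, A, valid.
.fitLogLinearMatrix <- function(M, te) {
  tc <- te - mean(te)
  sxx <- sum(tc^2)
  Y <- log(M)
  ybar <- rowMeans(Y)
  slope <- as.vector(Y %*% tc) / sxx
  A <- exp(ybar - slope * mean(te))
  T2 <- ifelse(slope < -1e-12, -1 / slope, NA_real_)
  cbind(T2 = T2, A = A, valid = as.numeric(slope < -1e-12))
}

#' Maximum-likelihood T2 fit under Rician noise for one pixel
#'
#' Jointly maximises \code{\link{ricianLogLik}} over (A, T2, sigma) by
#' bounded quasi-Newton (L-BFGS-B) on log-transformed parameters, so
#' positivity holds by construction. Initialisation defaults to the
#' log-linear fit for (A, T2) and the residual RMS for sigma. The achieved
#' log-likelihood is never below the log-likelihood at the initial point.
#'
#' @param magnitudes echo magnitudes, >= 0 (not all zero).
#' @param echoTimes strictly increasing echo times in ms, length >= 3.
#' @param init optional \code{c(A, T2, sigma)} starting point.
#' @param bounds list with elements \code{T2} (default \code{c(1, 500)} ms),
#'   \code{A} and \code{sigma} (defaults scaled to the data).
#' @param tol relative tolerance on the log-likelihood (default 1e-8).
#' @param sigmaFixed optional fixed noise scale; when given only (A, T2) are
#'   estimated.
#' @return list with \code{T2}, \code{A}, \code{sigma}, \code{loglik} and
#'   \code{converged}. On optimizer failure the log-linear estimate is
#'   returned with \code{converged = FALSE}; T2 estimates at the T2 bounds
#'   are likewise flagged.
#' @examples
#' te <- 15 + 7.7 * (0:8)
#' m <- simulateRicianSignal(500 * exp(-te / 60), sigma = 25, seed = 1)
#' fitRicianMLE(m, te)
#' @export
fitRicianMLE <- function(magnitudes, echoTimes, init = NULL, bounds = NULL,
                         tol = 1e-8, sigmaFixed = NULL) {
  if (length(echoTimes) < 3L) stop("need at least 3 echoes")
  if (length(magnitudes) != length(echoTimes))
    stop("'magnitudes' and 'echoTimes' must have equal length")
  if (any(magnitudes < 0)) stop("'magnitudes' must be >= 0")
  if (all(magnitudes == 0))
    return(list(T2 = NA_real_, A = NA_real_, sigma = NA_real_,
                loglik = NA_real_, converged = FALSE))

  t2lim <- if (!is.null(bounds$T2)) bounds$T2 else c(1, 500)
  Alim <- if (!is.null(bounds$A)) bounds$A else
    c(1e-6, 100 * max(magnitudes, 1e-6))
  slim <- if (!is.null(bounds$sigma)) bounds$sigma else
    c(1e-6, 10 * max(magnitudes, 1e-6))

  ll <- fitLogLinear(pmax(magnitudes, 1e-12), echoTimes)
  if (is.null(init)) {
    T20 <- if (isTRUE(ll$converged)) ll$T2 else mean(t2lim)
    A0 <- if (is.finite(ll$A) && ll$A > 0) ll$A else max(magnitudes)
    T20 <- min(max(T20, t2lim[1] * 1.01), t2lim[2] * 0.99)
    res <- magnitudes - A0 * exp(-echoTimes / T20)
    s0 <- max(sqrt(mean(res^2)), 1e-3 * max(magnitudes))
    init <- c(A0, T20, s0)
  }
  init <- pmin(pmax(init, c(Alim[1], t2lim[1], slim[1]) * 1.000001),
               c(Alim[2], t2lim[2], slim[2]) * 0.999999)

  # work on magnitudes floored away from zero: the log M term in the density
  # is parameter-free, so flooring only guards the numerics
  M <- pmax(magnitudes, 1e-12)
  te <- echoTimes

  if (is.null(sigmaFixed)) {
    fn <- function(th) .ricianNegLL(th, M, te)
    gr <- function(th) .ricianNegGrad(th, M, te)
    lower <- log(c(Alim[1], t2lim[1], slim[1]))
    upper <- log(c(Alim[2], t2lim[2], slim[2]))
    theta0 <- log(init)
  } else {
    if (sigmaFixed <= 0) stop("'sigmaFixed' must be > 0")
    fn <- function(th) .ricianNegLL(c(th, log(sigmaFixed)), M, te)
    gr <- function(th) .ricianNegGrad(c(th, log(sigmaFixed)), M, te)[1:2]
    lower <- log(c(Alim[1], t2lim[1]))
    upper <- log(c(Alim[2], t2lim[2]))
    theta0 <- log(init[1:2])
  }

  opt <- tryCatch(
    stats::optim(theta0, fn, gr, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(factr = tol / .Machine$double.eps,
                                               maxit = 200)),
    error = function(e) NULL)

  ll0 <- -fn(theta0)
  if (is.null(opt) || !is.finite(opt$value) || -opt$value < ll0) {
    # optimizer failure (or no ascent): fall back to the initial point
    par <- exp(theta0); okopt <- FALSE
  } else {
    par <- exp(opt$par)
    okopt <- opt$convergence == 0L
  }
  if (is.null(sigmaFixed)) {
    A <- par[1]; T2 <- par[2]; s <- par[3]
  } else {
    A <- par[1]; T2 <- par[2]; s <- sigmaFixed
  }
  atBound <- T2 <= t2lim[1] * 1.01 || T2 >= t2lim[2] * 0.999
  list(T2 = T2, A = A, sigma = s,
       loglik = ricianLogLik(c(A, T2, s), M, te),
       converged = okopt && !atBound)
}

#' Fit a pixel-wise T2 map over an image stack
#'
#' Applies the chosen per-pixel fit to every masked pixel of an
#' \code{\link{echoSeries}}. Unmasked pixels are NA in the result.
#'
#' @param series an \code{EchoSeries}.
#' @param method \code{"rician_mle"} (the reference method) or
#'   \code{"loglinear"} (fast baseline).
#' @param mask optional logical 3-D array overriding the series mask.
#' @param excludeFirstEcho drop the first echo before fitting (off by
#'   default).
#' @param ... passed to \code{\link{fitRicianMLE}}.
#' @return a \code{T2Map}.
#' @export
fitMap <- function(series, method = c("rician_mle", "loglinear"), mask = NULL,
                   excludeFirstEcho = FALSE, ...) {
  stopifnot(is(series, "EchoSeries"))
  method <- match.arg(method)
  if (is.null(mask)) mask <- series@mask
  if (!any(mask)) stop("empty mask: no pixels to fit")
  d <- dim(series@magnitudes)
  te <- series@echoTimes
  keepEcho <- if (excludeFirstEcho) -1L else seq_along(te)
  te <- te[keepEcho]

  flat <- matrix(series@magnitudes, prod(d[1:3]), d[4])[, keepEcho, drop = FALSE]
  idx <- which(as.vector(mask))
  M <- flat[idx, , drop = FALSE]

  mk <- function(fill = NA_real_) array(fill, d[1:3])
  t2 <- mk(); A <- mk(); sig <- mk(); lk <- mk()
  conv <- array(FALSE, d[1:3])

  if (method == "loglinear") {
    pos <- rowSums(M <= 0 | !is.finite(M)) == 0L
    if (any(pos)) {
      est <- .fitLogLinearMatrix(M[pos, , drop = FALSE], te)
      ii <- idx[pos]
      t2[ii] <- est[, "T2"]
      A[ii] <- est[, "A"]
      conv[ii] <- est[, "valid"] == 1 & !is.na(est[, "T2"]) &
        est[, "T2"] > 1 & est[, "T2"] <= 500
    }
  } else {
    for (j in seq_along(idx)) {
      f <- fitRicianMLE(M[j, ], te, ...)
      ii <- idx[j]
      t2[ii] <- f$T2; A[ii] <- f$A; sig[ii] <- f$sigma; lk[ii] <- f$loglik
      conv[ii] <- f$converged
    }
  }
  new("T2Map", t2 = t2, amplitude = A, sigma = sig, loglik = lk,
      converged = conv, method = if (method == "loglinear") "loglinear"
      else "rician_mle",
      pixelSpacing = series@pixelSpacing)
}
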