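#' Simulate Rician-distributed magnitude signal
#'
#' Draws magnitude-image noise realisations around noiseless signal
#' intensities \code{nu}: each output element is
#' \eqn{|\nu + n_1 + i n_2|} with independent Gaussian noise
#' \eqn{n_1, n_2 \sim N(0, \sigma^2)} in the two receiver channels. This is
#' the noise model of magnitude MR images, and the model assumed by
#' \code{\link{fitRicianMLE}}.
#'
#' @param nu numeric vector (or array) of noiseless magnitudes, all >= 0.
#' @param sigma Gaussian noise scale per channel, >= 0.
#' @param seed optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return numeric object of the same shape as \code{nu} with Rician noise
#'   applied. With \code{sigma = 0} the input is returned exactly.
#' @examples
#' simulateRicianSignal(c(100, 36.8), sigma = 0)          # exact identity
#' m <- simulateRicianSignal(rep(0, 1e4), sigma = 10, seed = 1)
#' mean(m)                                                # ~ 10 * sqrt(pi/2)
#' @export
simulateRicianSignal <- function(nu, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (any(nu < 0)) stop("'nu' must be non-negative elementwise")
  if (sigma == 0) return(nu)
  withSeed(seed, {
    re <- nu + rnorm(length(nu), 0, sigma)
    im <- rnorm(length(nu), 0, sigma)
    out <- sqrt(re * re + im * im)
    attributes(out) <- attributes(nu)
    out
  })
}

# log I0(x) computed from the exponentially scaled Bessel function; the
# asymptotic expansion takes over where besselI underflows (x > ~700).
logBesselI0 <- function(x) {
  out <- numeric(length(x))
  lo <- x < 700
  out[lo] <- log(besselI(x[lo], 0, expon.scaled = TRUE)) + x[lo]
  if (any(!lo)) {
    xl <- x[!lo]
    out[!lo] <- xl - 0.5 * log(2 * pi * xl) + log1p(1 / (8 * xl) + 9 / (128 * xl^2))
  }
  out
}

# I1(x)/I0(x), stable for large argument.
besselRatio <- function(x) {
  out <- numeric(length(x))
  lo <- x < 700
  out[lo] <- besselI(x[lo], 1, expon.scaled = TRUE) /
    besselI(x[lo], 0, expon.scaled = TRUE)
  if (any(!lo)) {
    xl <- x[!lo]
    out[!lo] <- 1 - 1 / (2 * xl) - 1 / (8 * xl^2)
  }
  out
}

#' Rician log-likelihood of a mono-exponential decay
#'
#' Log-likelihood of observed magnitudes under the Rician noise model with
#' noiseless decay \eqn{\nu_i = A \exp(-TE_i / T2)}:
#' \deqn{\sum_i \log M_i - 2\log\sigma - (M_i^2+\nu_i^2)/(2\sigma^2) +
#'   \log I_0(M_i \nu_i / \sigma^2)}
#' The Bessel term uses the exponentially scaled \eqn{I_0} so that large
#' arguments (high SNR) do not overflow.
#'
#' @param params numeric vector \code{c(A, T2, sigma)}, all > 0 (T2 in ms).
#' @param magnitudes observed magnitudes, one per echo.
#' @param echoTimes echo times in ms, same length as \code{magnitudes}.
#' @return scalar log-likelihood.
#' @export
ricianLogLik <- function(params, magnitudes, echoTimes) {
  if (length(params) != 3L || any(!is.finite(params)) || any(params <= 0))
    stop("'params' must be c(A, T2, sigma), all positive and finite")
  if (length(magnitudes) != length(echoTimes))
    stop("'magnitudes' and 'echoTimes' must have equal length")
  A <- params[1]; T2 <- params[2]; s <- params[3]
  nu <- A * exp(-echoTimes / T2)
  x <- magnitudes * nu / s^2
  sum(log(magnitudes) - 2 * log(s) -
        (magnitudes^2 + nu^2) / (2 * s^2) + logBesselI0(x))
}

# Negative log-likelihood and gradient on log-parameters (logA, logT2,
# logsigma): positivity by construction, smooth for quasi-Newton ascent.
.ricianNegLL <- function(theta, M, te) {
  A <- exp(theta[1]); T2 <- exp(theta[2]); s <- exp(theta[3])
  nu <- A * exp(-te / T2)
  x <- M * nu / s^2
  -sum(log(M) - 2 * log(s) - (M^2 + nu^2) / (2 * s^2) + logBesselI0(x))
}

.ricianNegGrad <- function(theta, M, te) {
  A <- exp(theta[1]); T2 <- exp(theta[2]); s <- exp(theta[3])
  nu <- A * exp(-te / T2)
  x <- M * nu / s^2
  R <- besselRatio(x)
  dl_dnu <- -nu / s^2 + (M / s^2) * R
  dl_ds <- -2 / s + (M^2 + nu^2) / s^3 - 2 * x * R / s
  c(-sum(dl_dnu * nu),                 # d/d logA
    -sum(dl_dnu * nu * te / T2),       # d/d logT2
    -sum(dl_ds) * s)                   # d/d logsigma
}
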