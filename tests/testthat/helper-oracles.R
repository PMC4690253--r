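# Independent oracles, deliberately naive, used to cross-check the package's
# optimised implementations.

# two-pass loop mean absolute deviation
naiveMAD <- function(x, logTransform = FALSE) {
  if (logTransform) x <- log(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + abs(v - m)
  s / length(x)
}

# brute-force pairwise AUC with half credit for ties
bruteAUC <- function(scores, y01) {
  ps <- scores[y01 == 1]
  ns <- scores[y01 == 0]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# exhaustive best Gini threshold for one feature (midpoints of consecutive
# sorted unique values; ties -> lowest threshold)
bruteBestThreshold <- function(x, y01, minLeaf = 1) {
  u <- sort(unique(x))
  if (length(u) < 2) return(NULL)
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (t in cand) {
    l <- y01[x < t]; r <- y01[x >= t]
    if (length(l) < minLeaf || length(r) < minLeaf) next
    g <- length(l) * 2 * mean(l) * (1 - mean(l)) +
      length(r) * 2 * mean(r) * (1 - mean(r))
    if (is.null(best) || g < best$g - 1e-12) best <- list(g = g, t = t)
  }
  best$t
}

# naive (unscaled-Bessel) Rician log-likelihood, valid only for small
# M*nu/sigma^2
naiveRicianLL <- function(params, M, te) {
  A <- params[1]; T2 <- params[2]; s <- params[3]
  nu <- A * exp(-te / T2)
  sum(log(M) - 2 * log(s) - (M^2 + nu^2) / (2 * s^2) +
        log(besselI(M * nu / s^2, 0)))
}

# simulate one pixel's echo magnitudes
simPixel <- function(A, T2, sigma, te) {
  nu <- A * exp(-te / T2)
  sqrt((nu + rnorm(length(te), 0, sigma))^2 + rnorm(length(te), 0, sigma)^2)
}

TE9 <- 15 + 7.7 * (0:8)
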