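#' Reference feature moments for healthy volunteers and acute myocarditis
#'
#' Mean and SD of the six subject-level features in the two classes, as
#' reported for the GraSE T2-mapping cohort (30 healthy volunteers, 31
#' acute-myocarditis patients). These are the default moments of the
#' feature-level cohort generator.
#'
#' @return data.frame with columns \code{feature}, \code{mean_hv},
#'   \code{sd_hv}, \code{mean_acm}, \code{sd_acm}.
#' @export
referenceFeatureMoments <- function() {
  data.frame(
    feature  = c("globalT2", "globalSD", "maxT2", "madT2", "maxSD", "madSD"),
    mean_hv  = c(58.7, 7.7, 69.6, 0.07, 12.5, 0.22),
    sd_hv    = c(4.2, 1.9, 8.5, 0.03, 4.2, 0.05),
    mean_acm = c(62.1, 8.5, 80.5, 0.09, 19.0, 0.29),
    sd_acm   = c(7.2, 2.4, 16.8, 0.02, 8.6, 0.06),
    stringsAsFactors = FALSE)
}

#' Default inter-feature correlation for the cohort generator
#'
#' Identity except for a correlation of 0.5 between maxT2 and madSD,
#' reflecting the collinearity observed between those two predictors.
#'
#' @param features feature names (order defines the matrix).
#' @param maxT2madSD correlation between maxT2 and madSD (default 0.5).
#' @return correlation matrix.
#' @export
defaultFeatureCorrelation <- function(features = referenceFeatureMoments()$feature,
                                      maxT2madSD = 0.5) {
  p <- length(features)
  R <- diag(p)
  dimnames(R) <- list(features, features)
  if (all(c("maxT2", "madSD") %in% features)) {
    R["maxT2", "madSD"] <- maxT2madSD
    R["madSD", "maxT2"] <- maxT2madSD
  }
  R
}

#' Generate a labelled feature-level cohort
#'
#' Draws per-subject feature vectors for the two classes from a truncated
#' multivariate normal: class-specific means/SDs (default: the reference
#' moments of \code{\link{referenceFeatureMoments}}), a shared correlation
#' matrix, and lower truncation at 0 for all features (T2 values and
#' dispersion statistics are non-negative); violating draws are rejected and
#' redrawn.
#'
#' @param nHV number of healthy-volunteer subjects (default 30).
#' @param nACM number of acute-myocarditis subjects (default 31).
#' @param moments data.frame in the format of
#'   \code{\link{referenceFeatureMoments}}.
#' @param correlation correlation matrix over \code{moments$feature}.
#' @param seed RNG seed.
#' @return data.frame with \code{subject_id}, \code{label} ("HV"/"ACM") and
#'   one column per feature.
#' @examples
#' head(generateCohortFeatures(5, 5, seed = 1))
#' @export
generateCohortFeatures <- function(nHV = 30, nACM = 31,
                                   moments = referenceFeatureMoments(),
                                   correlation = defaultFeatureCorrelation(moments$feature),
                                   seed = 1) {
  feats <- moments$feature
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation matrix is not positive definite")
  withSeed(seed, {
    drawClass <- function(n, mu, s, label, idOffset) {
      Sigma <- diag(s) %*% correlation %*% diag(s)
      X <- matrix(NA_real_, 0, length(feats))
      while (nrow(X) < n) {
        cand <- MASS::mvrnorm(n = 2 * (n - nrow(X)) + 8, mu = mu,
                              Sigma = Sigma)
        cand <- cand[rowSums(cand < 0) == 0L, , drop = FALSE]
        X <- rbind(X, cand)
      }
      X <- X[seq_len(n), , drop = FALSE]
      colnames(X) <- feats
      cbind(data.frame(subject_id = sprintf("%s%02d", label,
                                            idOffset + seq_len(n)),
                       label = label, stringsAsFactors = FALSE),
            as.data.frame(X))
    }
    rbind(drawClass(nHV, moments$mean_hv, moments$sd_hv, "HV", 0L),
          drawClass(nACM, moments$mean_acm, moments$sd_acm, "ACM", 0L))
  })
}
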