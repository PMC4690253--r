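#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of freedom
#' and a two-sided p-value (delegates to \code{stats::t.test}). The
#' degenerate case of two constant samples with equal means returns t = 0,
#' p = 1 rather than an error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list of class \code{welchTest}: \code{t}, \code{df}, \code{p},
#'   plus group means and SDs.
#' @examples
#' welchT(1:5, 2:6)   # t = -1, df = 8, p ~ 0.347
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  res <- tryCatch(t.test(a, b, var.equal = FALSE),
                  error = function(e) {
                    if (grepl("constant", conditionMessage(e)) &&
                        isTRUE(all.equal(mean(a), mean(b))))
                      return(NULL)
                    stop(e)
                  })
  if (is.null(res))
    out <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
  else
    out <- list(t = unname(res$statistic), df = unname(res$parameter),
                p = res$p.value)
  out$meanA <- mean(a); out$meanB <- mean(b)
  out$sdA <- sd(a); out$sdB <- sd(b)
  structure(out, class = "welchTest")
}

#' Wilcoxon rank-sum test with normal approximation Z
#'
#' Rank-sum test using midranks for ties. The test statistic W is the rank
#' sum of the first sample. A tie-corrected, continuity-corrected normal
#' approximation provides the Z score used for the effect size
#' r = Z / sqrt(N). The two-sided p-value comes from exact enumeration of
#' all rank assignments when the combined sample size is <= 12 (doubled
#' minimal tail, capped at 1), otherwise from the normal approximation.
#'
#' @param a,b numeric samples, each of length >= 1.
#' @param exact force (TRUE) or suppress (FALSE) exact enumeration; default
#'   NULL enumerates when \code{length(a) + length(b) <= 12}.
#' @return list of class \code{rankSumTest}: \code{W}, \code{Z}, \code{p},
#'   \code{exact}.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))   # exact two-sided p = 1/3
#' @export
wilcoxonRankSum <- function(a, b, exact = NULL) {
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("each sample needs n >= 1")
  n <- na + nb
  rk <- rank(c(a, b))
  W <- sum(rk[seq_len(na)])
  U <- W - na * (na + 1) / 2

  # tie-corrected variance of W under the null
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
  muW <- na * (n + 1) / 2
  varW <- na * nb / 12 * ((n + 1) - tieCorr)
  if (varW <= 0) {
    Z <- 0; pNorm <- 1
  } else {
    cc <- 0.5 * sign(W - muW)            # continuity correction toward the mean
    Z <- (W - muW - cc) / sqrt(varW)
    pNorm <- min(1, 2 * pnorm(-abs(Z)))
  }

  doExact <- if (is.null(exact)) n <= 12L else isTRUE(exact)
  if (doExact) {
    sums <- combn(n, na, function(ix) sum(rk[ix]))
    pLo <- mean(sums <= W)
    pHi <- mean(sums >= W)
    p <- min(1, 2 * min(pLo, pHi))
  } else {
    p <- pNorm
  }
  structure(list(W = W, Z = Z, p = p, exact = doExact, nA = na, nB = nb),
            class = "rankSumTest")
}

#' Effect size r from a test result
#'
#' Default: the rank-based effect size r = Z / sqrt(N) from a
#' \code{\link{wilcoxonRankSum}} result (the standard companion of rank-sum
#' tests). Alternative: r = sqrt(t^2 / (t^2 + df)) from a
#' \code{\link{welchT}} result. Which formula the original analysis used is
#' not documented, so both are available; \code{method = "z"} is the
#' package default.
#'
#' @param test a \code{rankSumTest} or \code{welchTest} object.
#' @param nTotal combined sample size N (required for \code{method = "z"}).
#' @param method \code{"z"} or \code{"t"}.
#' @return effect size r (always in [-1, 1]).
#' @export
effectSizeR <- function(test, nTotal = NULL, method = c("z", "t")) {
  method <- match.arg(method)
  if (method == "z") {
    if (!inherits(test, "rankSumTest"))
      stop("method 'z' needs a rankSumTest result")
    if (is.null(nTotal)) nTotal <- test$nA + test$nB
    if (nTotal <= 0) stop("'nTotal' must be positive")
    r <- test$Z / sqrt(nTotal)
  } else {
    if (!inherits(test, "welchTest"))
      stop("method 't' needs a welchTest result")
    r <- sqrt(test$t^2 / (test$t^2 + test$df))
  }
  max(-1, min(1, r))
}

#' Group comparison table over all features
#'
#' For each feature column, compares the two classes with the Welch t-test
#' and the Wilcoxon rank-sum test and reports group means +/- SDs, both
#' p-values and the rank-based effect size r -- the shape of a cohort
#' summary table.
#'
#' @param features data.frame with a \code{label} column ("HV"/"ACM") and
#'   numeric feature columns.
#' @param labelColumn name of the class column (default "label").
#' @param positiveClass class treated as the disease group (default "ACM").
#' @return data.frame, one row per feature.
#' @export
compareGroups <- function(features, labelColumn = "label",
                          positiveClass = "ACM") {
  lab <- features[[labelColumn]]
  if (length(unique(lab)) != 2L) stop("need exactly two classes")
  cols <- names(features)[vapply(features, is.numeric, TRUE)]
  pos <- features[lab == positiveClass, , drop = FALSE]
  neg <- features[lab != positiveClass, , drop = FALSE]
  do.call(rbind, lapply(cols, function(f) {
    a <- neg[[f]]; b <- pos[[f]]
    wt <- welchT(a, b)
    ws <- wilcoxonRankSum(a, b)
    data.frame(feature = f,
               mean_hv = mean(a), sd_hv = sd(a),
               mean_acm = mean(b), sd_acm = sd(b),
               t = wt$t, df = wt$df, p_welch = wt$p,
               W = ws$W, Z = ws$Z, p_wilcoxon = ws$p,
               effect_size_r = abs(effectSizeR(ws)),
               stringsAsFactors = FALSE)
  }))
}
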