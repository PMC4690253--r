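#' Random-forest variable importance (mean Gini decrease)
#'
#' Fits a random forest (bootstrap-resampled Gini trees with random feature
#' subsetting, via the randomForest package) and returns the per-feature
#' mean decrease in Gini impurity, the impurity-based importance used to
#' rank candidate diagnostic parameters.
#'
#' @param X data.frame of numeric features.
#' @param y binary labels (as in \code{\link{fitLogistic}}).
#' @param nTrees number of trees (default 500).
#' @param mtry features tried per split (default \code{floor(sqrt(p))}).
#' @param seed RNG seed (results are deterministic for a fixed seed).
#' @param positiveClass disease class of \code{y}.
#' @return named numeric vector of mean Gini decreases, one per feature.
#' @export
rfImportance <- function(X, y, nTrees = 500, mtry = NULL, seed = 1,
                         positiveClass = "ACM") {
  X <- as.data.frame(X)
  if (ncol(X) == 0L) stop("no features")
  yf <- if (is.logical(y) || is.numeric(y)) factor(as.integer(y != 0))
  else factor(as.character(y) == positiveClass)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  withSeed(seed, {
    rf <- randomForest::randomForest(x = X, y = yf, ntree = nTrees,
                                     mtry = mtry)
    imp <- randomForest::importance(rf, type = 2)
    setNames(as.numeric(imp), rownames(imp))
  })
}
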