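#' ROC analysis of a diagnostic score
#'
#' Sensitivity and specificity at every distinct score threshold (predict
#' positive when score >= threshold) and the area under the curve computed
#' by the Mann--Whitney pairwise formulation: the proportion of
#' (positive, negative) pairs in which the positive subject scores higher,
#' with half credit for ties.
#'
#' @param scores numeric diagnostic scores, higher = more disease-like.
#' @param labels binary labels; \code{positiveClass} codes disease.
#' @param positiveClass disease class (default "ACM").
#' @return object of class \code{rocResult}: \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{auc}.
#' @examples
#' rocCurve(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc   # 0.75
#' @export
rocCurve <- function(scores, labels, positiveClass = "ACM") {
  y <- if (is.logical(labels) || is.numeric(labels)) as.integer(labels != 0)
  else as.integer(as.character(labels) == positiveClass)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  # Mann-Whitney AUC from midranks (ties get half credit)
  rk <- rank(scores)
  auc <- (sum(rk[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) sum(scores >= t & y == 1) / nPos, 0)
  spec <- vapply(th, function(t) sum(scores < t & y == 0) / nNeg, 0)
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, nPos = nPos, nNeg = nNeg),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: %d positives vs %d negatives, AUC = %.3f\n",
              x$nPos, x$nNeg, x$auc))
  invisible(x)
}
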