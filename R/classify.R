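#' Combined madSD / maxT2 cut-off rule
#'
#' The diagnostic decision rule built on the two cut-offs estimated from
#' classification trees: madSD 0.22 and maxT2 68 ms. Under the default
#' \code{"and"} combination a subject is called ACM iff madSD > 0.22 AND
#' maxT2 > 68 ms (strict inequalities: boundary values count as healthy);
#' values below both cut-offs represent healthy myocardium. An \code{"or"}
#' variant is selectable.
#'
#' @param features data.frame with columns \code{madSD} and \code{maxT2}
#'   (one row per subject), or a single subject's named list.
#' @param madSDCut madSD cut-off (default 0.22).
#' @param maxT2Cut maxT2 cut-off in ms (default 68).
#' @param rule \code{"and"} (default) or \code{"or"}.
#' @return character vector of labels "ACM"/"HV".
#' @examples
#' applyCutoffRule(data.frame(madSD = c(0.29, 0.22), maxT2 = c(80.5, 68)))
#' @export
applyCutoffRule <- function(features, madSDCut = 0.22, maxT2Cut = 68,
                            rule = c("and", "or")) {
  rule <- match.arg(rule)
  features <- as.data.frame(features)
  for (f in c("madSD", "maxT2"))
    if (is.null(features[[f]]) || anyNA(features[[f]]))
      stop("missing feature '", f, "'")
  hi1 <- features$madSD > madSDCut
  hi2 <- features$maxT2 > maxT2Cut
  pos <- if (rule == "and") hi1 & hi2 else hi1 | hi2
  ifelse(pos, "ACM", "HV")
}

#' Layer-specific reference range for healthy myocardial T2
#'
#' Published healthy reference T2 values for the GraSE sequence at 1.5 T:
#' basal 56.7 +/- 4.1 ms, midventricular 58.1 +/- 4.2 ms, apical
#' 62.2 +/- 5.2 ms.
#'
#' @return data.frame with columns \code{level}, \code{mean}, \code{sd}.
#' @export
graseReferenceRange <- function() {
  data.frame(level = c("basal", "mid", "apical"),
             mean = c(56.7, 58.1, 62.2),
             sd = c(4.1, 4.2, 5.2), stringsAsFactors = FALSE)
}

#' Reference-range (mean + k * SD) baseline classifier
#'
#' The conventional segmental decision rule that the heterogeneity features
#' are compared against: a subject is called positive iff any segment's mean
#' T2 exceeds its layer's reference mean plus \code{k} standard deviations.
#'
#' @param table a segment table (\code{\link{segmentStatistics}}).
#' @param ref reference ranges, as \code{\link{graseReferenceRange}}.
#' @param k SD multiplier (2 and 3 are the conventional choices).
#' @return "ACM" if any segment exceeds its threshold, else "HV".
#' @export
referenceRangeClassify <- function(table, ref = graseReferenceRange(), k = 2) {
  if (k <= 0) stop("'k' must be positive")
  if (any(ref$sd <= 0)) stop("reference SDs must be positive")
  lvl <- match(table$level, ref$level)
  if (anyNA(lvl)) stop("unknown level: ",
                       paste(unique(table$level[is.na(lvl)]), collapse = ", "))
  thr <- ref$mean[lvl] + k * ref$sd[lvl]
  pos <- any(table$mean_T2_ms > thr, na.rm = TRUE)
  if (pos) "ACM" else "HV"
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits subjects into k folds stratified by class, refits the model on
#' each training set, predicts the held-out fold, and pools the accuracy.
#'
#' @param X data.frame of features.
#' @param y binary labels.
#' @param fitFun function(X, y) returning a fitted model.
#' @param predictFun function(model, X) returning predicted labels on the
#'   same coding as \code{y}.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return list: \code{accuracy} (pooled), \code{folds} (assignment),
#'   \code{predictions}.
#' @export
crossValidate <- function(X, y, fitFun, predictFun, k = 10, seed = 1) {
  n <- length(y)
  if (n < k) stop("need n >= k")
  X <- as.data.frame(X)
  folds <- integer(n)
  withSeed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  pred <- rep(NA_character_, n)
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test)) next
    if (length(unique(y[!test])) < 2L)
      stop("class absent from a training fold")
    m <- fitFun(X[!test, , drop = FALSE], y[!test])
    pred[test] <- as.character(predictFun(m, X[test, , drop = FALSE]))
  }
  list(accuracy = mean(pred == as.character(y)), folds = folds,
       predictions = pred)
}

#' Classification performance against true labels
#'
#' @param predicted,truth label vectors ("ACM"/"HV" or compatible).
#' @param positiveClass disease class (default "ACM").
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{falsePositiveRate}, \code{falseNegativeRate}.
#' @export
classificationPerformance <- function(predicted, truth,
                                      positiveClass = "ACM") {
  p <- as.character(predicted) == positiveClass
  t <- as.character(truth) == positiveClass
  list(sensitivity = sum(p & t) / sum(t),
       specificity = sum(!p & !t) / sum(!t),
       accuracy = mean(p == t),
       falsePositiveRate = sum(p & !t) / sum(!t),
       falseNegativeRate = sum(!p & t) / sum(t))
}
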