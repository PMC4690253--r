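#' Mean absolute deviation of segmental values
#'
#' The between-segment dispersion statistic underlying madT2 and madSD: with
#' \eqn{y_j = \log_e(x_j)} (when \code{logTransform = TRUE}) or
#' \eqn{y_j = x_j} otherwise,
#' \deqn{MAD = \sum_j |y_j - \bar y| / k , \qquad \bar y = \sum_j y_j / k.}
#' No re-scaling factor is applied. On the log scale the statistic is
#' invariant to multiplying all values by a constant; on the raw scale it is
#' invariant to adding a constant.
#'
#' @param values numeric vector, length k >= 2; strictly positive when
#'   \code{logTransform = TRUE}.
#' @param logTransform apply the natural log before computing deviations.
#' @return scalar mean absolute deviation (0 iff all values equal).
#' @examples
#' meanAbsDeviation(c(50, 60, 70, 80))                    # madT2-style: 10
#' meanAbsDeviation(exp(c(1, 3)), logTransform = TRUE)    # madSD-style: 1
#' @export
meanAbsDeviation <- function(values, logTransform = FALSE) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (logTransform) {
    if (any(values <= 0))
      stop("log transform requires strictly positive values")
    values <- log(values)
  }
  mean(abs(values - mean(values)))
}

#' Subject-level heterogeneity features from a segment table
#'
#' Condenses the 16 segmental (mean T2, pixel-SD) pairs of one subject into
#' the six diagnostic features: \code{globalT2} (mean segmental T2 averaged
#' over all 16 segments, ms), \code{globalSD} (mean pixel-SD, ms),
#' \code{maxT2} / \code{maxSD} (the single highest segmental value, ms),
#' \code{madT2} (mean absolute deviation of segmental T2 on the raw ms
#' scale) and \code{madSD} (mean absolute deviation of natural-log
#' pixel-SD, dimensionless).
#'
#' @param table a segment table from \code{\link{segmentStatistics}} (16
#'   rows for one subject).
#' @param allowPartial permit fewer than 16 usable segments; the MAD and
#'   means then use the available k (recorded in \code{n_segments}).
#' @param sdEpsilon floor applied to pixel-SD before the log (default 1e-6
#'   ms) so that a degenerate constant segment does not break madSD; a
#'   warning is emitted when the floor engages.
#' @param label subject class label stored alongside ("HV", "ACM" or
#'   "unknown").
#' @return one-row data.frame: \code{subject_id}, \code{label},
#'   \code{globalT2}, \code{globalSD}, \code{maxT2}, \code{maxSD},
#'   \code{madT2}, \code{madSD}, \code{n_segments}.
#' @export
computeFeatures <- function(table, allowPartial = FALSE, sdEpsilon = 1e-6,
                            label = "unknown") {
  need <- c("segment_id", "mean_T2_ms", "pixel_SD_ms", "n_pixels")
  if (!all(need %in% names(table)))
    stop("not a segment table: missing ", paste(setdiff(need, names(table)),
                                                collapse = ", "))
  usable <- !is.na(table$mean_T2_ms) & !is.na(table$pixel_SD_ms)
  if ("flagged" %in% names(table)) usable <- usable & !table$flagged
  tab <- table[usable, , drop = FALSE]
  k <- nrow(tab)
  if (k < 16L && !allowPartial)
    stop("subject has ", k, " usable segments; 16 required ",
         "(use allowPartial = TRUE to compute on available segments)")
  if (k < 2L) stop("need at least 2 usable segments")
  sdv <- tab$pixel_SD_ms
  if (any(sdv < sdEpsilon)) {
    warning("pixel-SD below ", sdEpsilon, " ms clamped before log transform")
    sdv <- pmax(sdv, sdEpsilon)
  }
  data.frame(
    subject_id = tab$subject_id[1], label = label,
    globalT2 = mean(tab$mean_T2_ms), globalSD = mean(sdv),
    maxT2 = max(tab$mean_T2_ms), maxSD = max(sdv),
    madT2 = meanAbsDeviation(tab$mean_T2_ms),
    madSD = meanAbsDeviation(sdv, logTransform = TRUE),
    n_segments = k, stringsAsFactors = FALSE)
}
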