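#' Myocardial contour set
#'
#' Endocardial/epicardial contours per short-axis slice, in mm world
#' coordinates, plus the anterior RV-insertion reference angle and the slice
#' level (basal / mid / apical) used by the AHA 16-segment model.
#'
#' @param slices list with one entry per slice, each a list with elements
#'   \code{endo} (N x 2 matrix, mm), \code{epi} (N x 2 matrix, mm),
#'   \code{rvAngle} (degrees) and \code{level} ("basal", "mid" or "apical").
#' @return object of class \code{contourSet}.
#' @export
contourSet <- function(slices) {
  for (s in slices) {
    if (!all(c("endo", "epi", "rvAngle", "level") %in% names(s)))
      stop("each slice needs endo, epi, rvAngle and level")
    if (!s$level %in% c("basal", "mid", "apical"))
      stop("level must be basal, mid or apical")
    if (!all(pracma::inpolygon(s$endo[, 1], s$endo[, 2],
                               s$epi[, 1], s$epi[, 2])))
      stop("endocardial contour must lie strictly inside the epicardial one")
  }
  structure(list(slices = slices), class = "contourSet")
}

#' @export
print.contourSet <- function(x, ...) {
  lv <- vapply(x$slices, `[[`, "", "level")
  cat(sprintf("contourSet: %d slices (%s)\n", length(x$slices),
              paste(lv, collapse = ", ")))
  invisible(x)
}

# pixel-center world coordinates of an imageSize^2 grid centred on the origin
.gridCoords <- function(imageSize, pixelSpacing) {
  u <- (seq_len(imageSize) - (imageSize + 1) / 2) * pixelSpacing
  list(x = u, y = u)
}

# polygon centroid (shoelace formula)
.polyCentroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Build AHA 16-segment label masks from contours
#'
#' Assigns every pixel whose center lies inside the epicardial and outside
#' the endocardial contour to an AHA segment. Basal and mid slices are split
#' into six 60-degree sectors, apical slices into four 90-degree sectors,
#' numbered counterclockwise from the anterior RV-insertion boundary
#' (anterior, anteroseptal, inferoseptal, inferior, inferolateral,
#' anterolateral). Segment ids are 1--6 basal, 7--12 mid, 13--16 apical.
#'
#' @param contours a \code{\link{contourSet}}.
#' @param imageSize pixels per image side of the target grid.
#' @param pixelSpacing pixel size in mm (grid centred on the origin).
#' @param clockwise set TRUE for image orientations in which anatomical
#'   counterclockwise appears clockwise in array coordinates.
#' @return integer 3-D array (x, y, slice) of labels, 0 = background.
#' @export
buildSegmentMasks <- function(contours, imageSize, pixelSpacing,
                              clockwise = FALSE) {
  stopifnot(inherits(contours, "contourSet"))
  nS <- length(contours$slices)
  g <- .gridCoords(imageSize, pixelSpacing)
  px <- rep(g$x, times = imageSize)
  py <- rep(g$y, each = imageSize)
  labels <- array(0L, c(imageSize, imageSize, nS))
  offsets <- c(basal = 0L, mid = 6L, apical = 12L)
  for (k in seq_len(nS)) {
    s <- contours$slices[[k]]
    inEpi <- pracma::inpolygon(px, py, s$epi[, 1], s$epi[, 2])
    inEndo <- pracma::inpolygon(px, py, s$endo[, 1], s$endo[, 2])
    annulus <- inEpi & !inEndo
    if (!any(annulus)) stop("empty annulus on slice ", k)
    ctr <- .polyCentroid(s$epi)
    ang <- atan2(py[annulus] - ctr[2], px[annulus] - ctr[1]) * 180 / pi
    rel <- if (clockwise) (s$rvAngle - ang) %% 360 else (ang - s$rvAngle) %% 360
    nseg <- if (s$level == "apical") 4L else 6L
    sector <- pmin(floor(rel / (360 / nseg)), nseg - 1L) + 1L
    lab <- integer(length(px))
    lab[annulus] <- sector + offsets[[s$level]]
    labels[, , k] <- lab
  }
  labels
}

#' Slice level of each AHA segment id
#'
#' @param segmentId integer vector of segment ids 1--16.
#' @return character vector: "basal" (1--6), "mid" (7--12), "apical" (13--16).
#' @export
segmentLevel <- function(segmentId) {
  c(rep("basal", 6), rep("mid", 6), rep("apical", 4))[segmentId]
}

#' Per-segment T2 statistics from a fitted map
#'
#' Pools all converged pixels sharing an AHA segment id (slices of the same
#' level are pooled) and records the arithmetic mean T2 and the sample
#' standard deviation of pixel T2 values ("pixel-SD", n-1 denominator) --
#' the within-segment heterogeneity measure that the madSD feature is built
#' on -- plus the pixel count.
#'
#' @param map a \code{T2Map} (or a bare 3-D numeric array of T2 values, in
#'   which case every finite pixel counts as converged).
#' @param labels integer 3-D label array from
#'   \code{\link{buildSegmentMasks}}.
#' @param subjectId identifier stored in the table (default "subject").
#' @param minPixels segments with fewer converged pixels are flagged
#'   (default 10).
#' @return data.frame with 16 rows: \code{subject_id}, \code{segment_id},
#'   \code{mean_T2_ms}, \code{pixel_SD_ms}, \code{n_pixels}, \code{level},
#'   \code{flagged}.
#' @export
segmentStatistics <- function(map, labels, subjectId = "subject",
                              minPixels = 10) {
  if (is(map, "T2Map")) {
    t2 <- map@t2
    ok <- map@converged & !is.na(map@t2)
  } else {
    t2 <- map
    ok <- is.finite(map)
  }
  if (!identical(dim(t2), dim(labels)))
    stop("label array must match the map grid")
  out <- data.frame(subject_id = subjectId, segment_id = 1:16,
                    mean_T2_ms = NA_real_, pixel_SD_ms = NA_real_,
                    n_pixels = 0L, level = segmentLevel(1:16),
                    flagged = TRUE, stringsAsFactors = FALSE)
  use <- ok & labels > 0L
  lab <- labels[use]
  val <- t2[use]
  for (sid in 1:16) {
    v <- val[lab == sid]
    n <- length(v)
    out$n_pixels[sid] <- n
    if (n >= 1L) out$mean_T2_ms[sid] <- mean(v)
    if (n >= 2L) out$pixel_SD_ms[sid] <- sd(v)
    out$flagged[sid] <- n < minPixels
  }
  out
}
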