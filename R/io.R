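#' Write / read an EchoSeries as NIfTI plus JSON sidecar
#'
#' The magnitude stack is stored as a 4-D NIfTI-1 volume (x, y, slice,
#' echo), the mask as a 3-D volume, and the echo times and pixel spacing in
#' a JSON sidecar.
#'
#' @param series an \code{EchoSeries}.
#' @param dir output directory (created if needed).
#' @return \code{writeEchoSeries}: the directory, invisibly;
#'   \code{readEchoSeries}: the reconstructed \code{EchoSeries}.
#' @export
writeEchoSeries <- function(series, dir) {
  stopifnot(is(series, "EchoSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(series@magnitudes, file.path(dir, "echoes.nii.gz"))
  RNifti::writeNifti(array(as.integer(series@mask), dim(series@mask)),
                     file.path(dir, "mask.nii.gz"))
  jsonlite::write_json(
    list(echo_times_ms = series@echoTimes,
         pixel_spacing_mm = series@pixelSpacing),
    file.path(dir, "echoes.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname writeEchoSeries
#' @export
readEchoSeries <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "echoes.json"),
                              simplifyVector = TRUE)
  mags <- .niftiArray(file.path(dir, "echoes.nii.gz"))
  mask <- .niftiArray(file.path(dir, "mask.nii.gz")) != 0
  echoSeries(mags, side$echo_times_ms, mask = mask,
             pixelSpacing = side$pixel_spacing_mm[1])
}

# read a NIfTI volume as a plain numeric array
.niftiArray <- function(path) {
  x <- RNifti::readNifti(path)
  array(as.vector(x), dim(x))
}

#' Write / read a fitted T2Map
#'
#' T2 (ms), amplitude, noise scale, log-likelihood and convergence flags are
#' stored as NIfTI volumes, with a JSON fit report (method, pixel counts).
#'
#' @param map a \code{T2Map}.
#' @param dir output directory.
#' @return \code{writeT2Map}: the directory, invisibly; \code{readT2Map}:
#'   the reconstructed \code{T2Map}.
#' @export
writeT2Map <- function(map, dir) {
  stopifnot(is(map, "T2Map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(map@t2, file.path(dir, "t2.nii.gz"))
  RNifti::writeNifti(map@amplitude, file.path(dir, "amplitude.nii.gz"))
  RNifti::writeNifti(map@sigma, file.path(dir, "sigma.nii.gz"))
  RNifti::writeNifti(map@loglik, file.path(dir, "loglik.nii.gz"))
  RNifti::writeNifti(array(as.integer(map@converged), dim(map@converged)),
                     file.path(dir, "converged.nii.gz"))
  jsonlite::write_json(
    list(method = map@method, pixel_spacing_mm = map@pixelSpacing,
         n_fitted = sum(!is.na(map@t2)), n_converged = sum(map@converged)),
    file.path(dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeT2Map
#' @export
readT2Map <- function(dir) {
  rep <- jsonlite::read_json(file.path(dir, "fit_report.json"),
                             simplifyVector = TRUE)
  rd <- function(f) .niftiArray(file.path(dir, f))
  new("T2Map", t2 = rd("t2.nii.gz"), amplitude = rd("amplitude.nii.gz"),
      sigma = rd("sigma.nii.gz"), loglik = rd("loglik.nii.gz"),
      converged = rd("converged.nii.gz") != 0, method = rep$method,
      pixelSpacing = rep$pixel_spacing_mm)
}

#' Write / read myocardial contours as JSON
#'
#' Schema: \code{\{"slices": [\{"endo": [[x,y], ...], "epi": [[x,y], ...],
#' "rv_angle_deg": a, "level": "basal"\}, ...]\}} with coordinates in mm.
#'
#' @param contours a \code{\link{contourSet}}.
#' @param path JSON file path.
#' @return \code{writeContours}: the path, invisibly; \code{readContours}:
#'   a \code{contourSet}.
#' @export
writeContours <- function(contours, path) {
  stopifnot(inherits(contours, "contourSet"))
  jsonlite::write_json(
    list(slices = lapply(contours$slices, function(s)
      list(endo = unname(apply(s$endo, 1, c, simplify = FALSE)),
           epi = unname(apply(s$epi, 1, c, simplify = FALSE)),
           rv_angle_deg = s$rvAngle, level = s$level))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(z) if (is.matrix(z)) z else do.call(rbind, z)
  contourSet(lapply(seq_len(nrow(raw$slices)), function(i) {
    list(endo = toMat(raw$slices$endo[[i]]),
         epi = toMat(raw$slices$epi[[i]]),
         rvAngle = raw$slices$rv_angle_deg[i],
         level = raw$slices$level[i])
  }))
}

#' Write / read segment tables and feature tables as CSV
#'
#' Feature CSVs use the column order \code{subject_id, label, globalT2,
#' globalSD, maxT2, maxSD, madT2, madSD}.
#'
#' @param table data.frame to write.
#' @param path CSV file path.
#' @return readers return the data.frame; writers the path, invisibly.
#' @export
writeSegmentTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSegmentTable
#' @export
readSegmentTable <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname writeSegmentTable
#' @export
writeFeatures <- function(table, path) {
  cols <- c("subject_id", "label", "globalT2", "globalSD", "maxT2", "maxSD",
            "madT2", "madSD")
  write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSegmentTable
#' @export
readFeatures <- function(path) read.csv(path, stringsAsFactors = FALSE)
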