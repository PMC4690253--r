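#' @import methods
NULL

#' LesionSpec: a focal inflammatory lesion in the phantom myocardium
#'
#' A wedge-shaped (angular-sector) region of elevated T2 inside the annular
#' myocardium, emulating focal edema in acute myocarditis. The lesion sits
#' subepicardially and extends inward over a fraction of the wall; its angular
#' edge is smoothed by a raised-cosine ramp so segmental statistics respond
#' gradually to partial involvement.
#'
#' @slot slices integer indices of the short-axis slices involved.
#' @slot centerDeg angular position of the lesion center (degrees).
#' @slot extentDeg angular extent (degrees), in (0, 360].
#' @slot transmuralFraction fraction of the wall thickness involved, in (0, 1].
#' @slot deltaT2 T2 elevation in the lesion core (ms), >= 0; focal edema is
#'   typically 10--20 ms above remote myocardium.
#' @slot textureFactor multiplier on the within-tissue texture SD inside the
#'   lesion (>= 1); inflamed tissue is more heterogeneous than remote
#'   myocardium, which is what elevates pixel-SD in affected segments.
#' @export
setClass("LesionSpec",
  representation(slices = "integer", centerDeg = "numeric",
                 extentDeg = "numeric", transmuralFraction = "numeric",
                 deltaT2 = "numeric", textureFactor = "numeric"))

setValidity("LesionSpec", function(object) {
  msg <- NULL
  if (length(object@slices) < 1L || any(object@slices < 1L))
    msg <- c(msg, "'slices' must be positive indices")
  if (!(object@extentDeg > 0 && object@extentDeg <= 360))
    msg <- c(msg, "'extentDeg' must be in (0, 360]")
  if (!(object@transmuralFraction > 0 && object@transmuralFraction <= 1))
    msg <- c(msg, "'transmuralFraction' must be in (0, 1]")
  if (object@deltaT2 < 0) msg <- c(msg, "'deltaT2' must be >= 0")
  if (object@textureFactor < 1) msg <- c(msg, "'textureFactor' must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LesionSpec
#'
#' @param slices slice indices involved (1-based).
#' @param centerDeg angular center in degrees.
#' @param extentDeg angular extent in degrees, in (0, 360].
#' @param transmuralFraction fraction of wall depth involved from the
#'   epicardial side, in (0, 1].
#' @param deltaT2 T2 elevation in ms (typically 10--20 for acute edema).
#' @param textureFactor within-lesion texture SD multiplier (default 1.8).
#' @return a \code{LesionSpec} object.
#' @examples
#' lesionSpec(slices = 3:4, centerDeg = 30, extentDeg = 60,
#'            transmuralFraction = 1, deltaT2 = 15)
#' @export
lesionSpec <- function(slices, centerDeg, extentDeg, transmuralFraction = 1,
                       deltaT2 = 15, textureFactor = 1.8) {
  new("LesionSpec", slices = as.integer(slices), centerDeg = centerDeg,
      extentDeg = extentDeg, transmuralFraction = transmuralFraction,
      deltaT2 = deltaT2, textureFactor = textureFactor)
}

#' PhantomSpec: geometry, tissue and acquisition parameters of one phantom
#'
#' Describes a synthetic short-axis cardiac acquisition: an annular
#' left-ventricular myocardium on each of \code{nSlices} slices, imaged with a
#' multi-echo GraSE-style readout (default nine echoes, TE1 = 15 ms,
#' delta TE = 7.7 ms) and Rician magnitude noise.
#'
#' @slot imageSize pixels per image side.
#' @slot pixelSpacing in-plane pixel size in mm.
#' @slot endoRadius endocardial radius in mm.
#' @slot wallThickness myocardial wall thickness in mm.
#' @slot nSlices number of short-axis slices (>= 3; levels basal/mid/apical).
#' @slot rvAngle reference angle (degrees) of the anterior RV-insertion
#'   boundary that anchors AHA segment 1.
#' @slot baselineT2 subject-global myocardial T2 in ms.
#' @slot levelOffsets named numeric of additive T2 offsets (ms) for the
#'   basal/mid/apical levels, reflecting the apex-ward T2 increase seen in
#'   healthy reference values.
#' @slot segmentSD between-segment biological T2 scatter (ms, SD).
#' @slot textureSD median within-segment pixel T2 texture SD (ms).
#' @slot textureScatter lognormal sdlog of the per-segment texture SD; drives
#'   between-segment heterogeneity of pixel-SD (hence madSD) in health.
#' @slot snr amplitude-to-noise ratio A/sigma at TE = 0 (Inf = noiseless).
#' @slot echoTimes echo times in ms, strictly increasing.
#' @slot lesions list of \code{LesionSpec} objects.
#' @slot seed RNG seed for the subject.
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", pixelSpacing = "numeric",
                 endoRadius = "numeric", wallThickness = "numeric",
                 nSlices = "integer", rvAngle = "numeric",
                 baselineT2 = "numeric", levelOffsets = "numeric",
                 segmentSD = "numeric", textureSD = "numeric",
                 textureScatter = "numeric", snr = "numeric",
                 echoTimes = "numeric", lesions = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (object@endoRadius <= 0) msg <- c(msg, "'endoRadius' must be > 0")
  if (object@wallThickness <= 0) msg <- c(msg, "'wallThickness' must be > 0")
  if (object@nSlices < 3L) msg <- c(msg, "'nSlices' must be >= 3")
  if (length(object@echoTimes) < 3L || any(diff(object@echoTimes) <= 0))
    msg <- c(msg, "'echoTimes' must be strictly increasing, length >= 3")
  if (object@snr <= 0) msg <- c(msg, "'snr' must be > 0")
  if (object@baselineT2 <= 0) msg <- c(msg, "'baselineT2' must be > 0")
  if (!all(vapply(object@lesions, is, TRUE, "LesionSpec")))
    msg <- c(msg, "'lesions' must be a list of LesionSpec objects")
  if (!all(c("basal", "mid", "apical") %in% names(object@levelOffsets)))
    msg <- c(msg, "'levelOffsets' needs named entries basal/mid/apical")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PhantomSpec
#'
#' Defaults mirror the emulated acquisition (2 x 2 mm in-plane resolution,
#' six short-axis slices, nine echoes TE = 15 + 7.7 k ms) and a healthy
#' myocardium with global T2 around 58.7 ms. The geometry (25 mm endocardial
#' radius, 10 mm wall) yields roughly 470 myocardial pixels per slice, i.e.
#' >= 150 pixels per pooled AHA segment, enough for stable pixel-SD.
#'
#' @param imageSize pixels per side (default 128).
#' @param pixelSpacing mm per pixel (default 2).
#' @param endoRadius endocardial radius in mm (default 25).
#' @param wallThickness wall thickness in mm (default 10).
#' @param nSlices number of slices (default 6).
#' @param rvAngle anterior RV-insertion reference angle in degrees
#'   (default 60).
#' @param baselineT2 global myocardial T2 in ms (default 58.7, the healthy
#'   reference mean).
#' @param levelOffsets per-level T2 offsets in ms; defaults reproduce the
#'   basal/mid/apical gradient of published healthy reference values
#'   (56.7 / 58.1 / 62.2 ms) relative to their mean.
#' @param segmentSD between-segment T2 scatter SD in ms (default 5.5).
#' @param textureSD median within-segment pixel texture SD in ms (default 6).
#' @param textureScatter lognormal sdlog of per-segment texture SD
#'   (default 0.4); see the methods vignette for the calibration rationale.
#' @param snr amplitude/noise at TE = 0 (default 40; use \code{Inf} for a
#'   noiseless phantom).
#' @param echoTimes echo times in ms (default \code{15 + 7.7 * 0:8}).
#' @param lesions list of \code{\link{lesionSpec}} objects (default none).
#' @param seed subject RNG seed (default 1).
#' @return a \code{PhantomSpec} object.
#' @examples
#' spec <- phantomSpec(seed = 7, lesions = list(
#'   lesionSpec(slices = 3:4, centerDeg = 45, extentDeg = 80, deltaT2 = 15)))
#' @export
phantomSpec <- function(imageSize = 128, pixelSpacing = 2, endoRadius = 25,
                        wallThickness = 10, nSlices = 6, rvAngle = 60,
                        baselineT2 = 58.7,
                        levelOffsets = c(basal = -2.3, mid = -0.9, apical = 3.2),
                        segmentSD = 5.5, textureSD = 6, textureScatter = 0.4,
                        snr = 40, echoTimes = 15 + 7.7 * (0:8),
                        lesions = list(), seed = 1) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      pixelSpacing = pixelSpacing, endoRadius = endoRadius,
      wallThickness = wallThickness, nSlices = as.integer(nSlices),
      rvAngle = rvAngle, baselineT2 = baselineT2, levelOffsets = levelOffsets,
      segmentSD = segmentSD, textureSD = textureSD,
      textureScatter = textureScatter, snr = snr, echoTimes = echoTimes,
      lesions = lesions, seed = as.integer(seed))
}

#' EchoSeries: a multi-echo magnitude image stack
#'
#' The raw input to T2 fitting: a 4-D array of non-negative magnitudes
#' indexed (x, y, slice, echo) together with the echo times and an optional
#' myocardial mask.
#'
#' @slot magnitudes 4-D numeric array (x, y, slice, echo), >= 0.
#' @slot echoTimes echo times in ms, strictly increasing, length >= 3.
#' @slot mask logical 3-D array (x, y, slice) flagging pixels of interest.
#' @slot pixelSpacing in-plane pixel size in mm.
#' @export
setClass("EchoSeries",
  representation(magnitudes = "array", echoTimes = "numeric",
                 mask = "array", pixelSpacing = "numeric"))

setValidity("EchoSeries", function(object) {
  d <- dim(object@magnitudes)
  msg <- NULL
  if (length(d) != 4L) msg <- c(msg, "'magnitudes' must be a 4-D array")
  if (length(object@echoTimes) < 3L || any(diff(object@echoTimes) <= 0))
    msg <- c(msg, "'echoTimes' must be strictly increasing, length >= 3")
  if (length(d) == 4L && d[4] != length(object@echoTimes))
    msg <- c(msg, "4th dimension must match length(echoTimes)")
  if (min(object@magnitudes) < 0) msg <- c(msg, "'magnitudes' must be >= 0")
  if (length(d) == 4L && !identical(dim(object@mask), d[1:3]))
    msg <- c(msg, "'mask' must match the image grid (x, y, slice)")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EchoSeries
#'
#' @param magnitudes 4-D array (x, y, slice, echo) of magnitudes.
#' @param echoTimes echo times in ms.
#' @param mask optional logical 3-D array; defaults to all-TRUE.
#' @param pixelSpacing pixel size in mm (default 2).
#' @return an \code{EchoSeries}.
#' @export
echoSeries <- function(magnitudes, echoTimes, mask = NULL, pixelSpacing = 2) {
  if (is.null(mask))
    mask <- array(TRUE, dim(magnitudes)[1:3])
  new("EchoSeries", magnitudes = magnitudes, echoTimes = echoTimes,
      mask = mask, pixelSpacing = pixelSpacing)
}

#' GroundTruth: per-pixel truth of a simulated phantom subject
#'
#' @slot trueT2 3-D array of true T2 (ms); NA outside the myocardium.
#' @slot trueA 3-D array of true amplitude at TE = 0.
#' @slot sigma Rician noise scale used.
#' @slot lesionMask logical 3-D array of lesion-core pixels.
#' @slot segmentLabels integer 3-D array of AHA labels 1--16 (0 = background).
#' @export
setClass("GroundTruth",
  representation(trueT2 = "array", trueA = "array", sigma = "numeric",
                 lesionMask = "array", segmentLabels = "array"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  myo <- object@segmentLabels > 0L
  if (any(object@lesionMask & !myo))
    msg <- c(msg, "lesion mask must lie inside the myocardium")
  if (any(!is.na(object@trueT2[myo]) & object@trueT2[myo] <= 0))
    msg <- c(msg, "true T2 must be positive inside the myocardium")
  if (is.null(msg)) TRUE else msg
})

#' T2Map: a fitted pixel-wise T2 parameter map
#'
#' @slot t2 3-D array of fitted T2 in ms (NA where absent/not fitted).
#' @slot amplitude 3-D array of fitted amplitude at TE = 0.
#' @slot sigma 3-D array of fitted Rician noise scale (NA for log-linear).
#' @slot loglik 3-D array of achieved log-likelihood (NA for log-linear).
#' @slot converged logical 3-D array; FALSE where the fit failed or hit a
#'   bound.
#' @slot method "loglinear" or "rician_mle".
#' @slot pixelSpacing in-plane pixel size in mm.
#' @export
setClass("T2Map",
  representation(t2 = "array", amplitude = "array", sigma = "array",
                 loglik = "array", converged = "array", method = "character",
                 pixelSpacing = "numeric"))

setValidity("T2Map", function(object) {
  msg <- NULL
  if (!object@method %in% c("loglinear", "rician_mle"))
    msg <- c(msg, "'method' must be 'loglinear' or 'rician_mle'")
  ok <- object@converged & !is.na(object@t2)
  if (any(object@t2[ok] <= 0)) msg <- c(msg, "converged T2 must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "EchoSeries", function(object) {
  d <- dim(object@magnitudes)
  cat(sprintf("EchoSeries: %d x %d pixels, %d slices, %d echoes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TE (ms): %s\n", paste(signif(object@echoTimes, 4),
                                       collapse = ", ")))
  cat(sprintf("  masked pixels: %d\n", sum(object@mask)))
})

setMethod("show", "T2Map", function(object) {
  ok <- object@converged & !is.na(object@t2)
  cat(sprintf("T2Map (%s): %d fitted pixels, %d converged\n", object@method,
              sum(!is.na(object@t2)), sum(ok)))
  if (any(ok))
    cat(sprintf("  T2 range (converged): %.1f -- %.1f ms, median %.1f ms\n",
                min(object@t2[ok]), max(object@t2[ok]),
                stats::median(object@t2[ok])))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d px @ %.1f mm, %d slices, T2 %.1f ms, SNR %.0f, %d lesion(s)\n",
    object@imageSize, object@pixelSpacing, object@nSlices, object@baselineT2,
    object@snr, length(object@lesions)))
})

#' Accessors for EchoSeries and T2Map
#'
#' @param object an \code{EchoSeries} or \code{T2Map}.
#' @return \code{echoTimes()}: the echo-time vector (ms);
#'   \code{seriesMagnitudes()}: the 4-D magnitude array;
#'   \code{seriesMask()}: the logical mask; \code{t2Values()}: the 3-D array
#'   of fitted T2 (ms); \code{fitConverged()}: the logical convergence array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
echoTimes <- function(object) object@echoTimes
#' @rdname accessors
#' @export
seriesMagnitudes <- function(object) object@magnitudes
#' @rdname accessors
#' @export
seriesMask <- function(object) object@mask
#' @rdname accessors
#' @export
t2Values <- function(object) object@t2
#' @rdname accessors
#' @export
fitConverged <- function(object) object@converged
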