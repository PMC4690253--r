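# Circle-polygon contours (90 vertices) for the annular phantom myocardium.
.circle <- function(r, n = 90) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

# slice -> level assignment: consecutive thirds (1,2 basal; 3,4 mid; 5,6
# apical for six slices), matching slices evenly distributed across the LV
.sliceLevels <- function(nSlices) {
  c("basal", "mid", "apical")[cut(seq_len(nSlices), 3, labels = FALSE)]
}

#' Contours of a phantom subject
#'
#' Circular endo/epicardial contours implied by a \code{\link{phantomSpec}},
#' one pair per slice, with the spec's RV-insertion angle and a
#' basal/mid/apical level split in consecutive thirds.
#'
#' @param spec a \code{PhantomSpec}.
#' @return a \code{\link{contourSet}}.
#' @export
phantomContours <- function(spec) {
  lv <- .sliceLevels(spec@nSlices)
  epiR <- spec@endoRadius + spec@wallThickness
  contourSet(lapply(seq_len(spec@nSlices), function(k) {
    list(endo = .circle(spec@endoRadius), epi = .circle(epiR),
         rvAngle = spec@rvAngle, level = lv[k])
  }))
}

#' Generate one phantom subject: multi-echo images plus ground truth
#'
#' Builds an annular myocardium on each slice, assigns every myocardial pixel
#' a true T2 composed of the subject baseline, a per-level offset, a
#' per-segment biological offset, within-segment texture (per-segment texture
#' SD drawn lognormally, the source of between-segment pixel-SD
#' heterogeneity), and any lesion elevation; then synthesises the multi-echo
#' magnitude series \eqn{A\exp(-TE/T2)} with Rician noise at the specified
#' SNR.
#'
#' Lesions are angular wedges with a raised-cosine angular edge (about two
#' pixels wide) extending from the epicardium over \code{transmuralFraction}
#' of the wall; pixels outside the myocardium are clipped, with a warning if
#' a lesion vanishes entirely.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{series} (an \code{EchoSeries}), \code{truth}
#'   (a \code{GroundTruth}) and \code{contours} (a \code{contourSet}).
#' @examples
#' sub <- generatePhantomSubject(phantomSpec(imageSize = 48, seed = 7))
#' sub$series
#' @export
generatePhantomSubject <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@imageSize
    nS <- spec@nSlices
    contours <- phantomContours(spec)
    labels <- .phantomLabels(spec)
    lv <- .sliceLevels(nS)
    epiR <- spec@endoRadius + spec@wallThickness

    g <- .gridCoords(n, spec@pixelSpacing)
    px <- matrix(rep(g$x, times = n), n, n)
    py <- matrix(rep(g$y, each = n), n, n)
    r <- sqrt(px^2 + py^2)
    ang <- atan2(py, px) * 180 / pi

    segOffset <- rnorm(16, 0, spec@segmentSD)
    segTexSD <- if (spec@textureSD > 0)
      exp(rnorm(16, log(spec@textureSD), spec@textureScatter))
    else rep(0, 16)

    smooth <- array(NA_real_, c(n, n, nS))   # baseline + level + segment offset
    texDev <- array(0, c(n, n, nS))          # within-segment texture deviation
    texMult <- array(1, c(n, n, nS))         # lesion texture amplification
    deltaSum <- array(0, c(n, n, nS))        # lesion T2 elevation
    lesW <- array(0, c(n, n, nS))
    for (k in seq_len(nS)) {
      lab <- labels[, , k]
      myo <- lab > 0L
      base <- spec@baselineT2 + spec@levelOffsets[[lv[k]]]
      sm <- matrix(NA_real_, n, n)
      sm[myo] <- base + segOffset[lab[myo]]
      smooth[, , k] <- sm
      td <- matrix(0, n, n)
      td[myo] <- rnorm(sum(myo), 0, segTexSD[lab[myo]])
      texDev[, , k] <- td
    }
    edgeMM <- 2 * spec@pixelSpacing   # raised-cosine edge width (arc length)
    for (les in spec@lesions) {
      w <- array(0, c(n, n, nS))
      for (k in intersect(les@slices, seq_len(nS))) {
        dAng <- abs(((ang - les@centerDeg + 180) %% 360) - 180)
        # signed arc distance (mm) past the nominal wedge boundary; the
        # raised-cosine ramp is centred on the boundary so the half-weight
        # contour coincides with the nominal angular extent
        arcOut <- r * (dAng - les@extentDeg / 2) * pi / 180
        wk <- ifelse(arcOut <= -edgeMM / 2, 1,
                     ifelse(arcOut >= edgeMM / 2, 0,
                            0.5 - 0.5 * sin(pi * arcOut / edgeMM)))
        wk[r < epiR - les@transmuralFraction * spec@wallThickness] <- 0
        wk[labels[, , k] == 0L] <- 0
        w[, , k] <- wk
      }
      if (all(w == 0))
        warning("lesion at ", les@centerDeg,
                " deg covers no myocardial pixels after clipping")
      deltaSum <- deltaSum + les@deltaT2 * w
      texMult <- pmax(texMult, 1 + (les@textureFactor - 1) * w)
      lesW <- pmax(lesW, w)
    }
    myo3 <- labels > 0L
    trueT2 <- smooth + texDev * texMult + deltaSum
    trueT2[myo3] <- pmax(trueT2[myo3], 1)

    A0 <- 500
    trueA <- array(0, c(n, n, nS))
    trueA[myo3] <- A0
    sigma <- if (is.infinite(spec@snr)) 0 else A0 / spec@snr

    te <- spec@echoTimes
    nu <- array(0, c(n, n, nS, length(te)))
    for (e in seq_along(te)) {
      slab <- trueA
      slab[myo3] <- trueA[myo3] * exp(-te[e] / trueT2[myo3])
      nu[, , , e] <- slab
    }
    mags <- simulateRicianSignal(nu, sigma)

    series <- echoSeries(mags, te, mask = myo3,
                         pixelSpacing = spec@pixelSpacing)
    truth <- new("GroundTruth", trueT2 = trueT2, trueA = trueA, sigma = sigma,
                 lesionMask = lesW > 0.5 & myo3, segmentLabels = labels)
    list(series = series, truth = truth, contours = contours)
  })
}
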