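# cache of segment-label arrays keyed by geometry, so cohorts sharing one
# phantom geometry do not redo point-in-polygon work
.labelCache <- new.env(parent = emptyenv())

.phantomLabels <- function(spec) {
  key <- paste(spec@imageSize, spec@pixelSpacing, spec@endoRadius,
               spec@wallThickness, spec@nSlices, spec@rvAngle, sep = "|")
  if (!is.null(.labelCache[[key]])) return(.labelCache[[key]])
  lab <- buildSegmentMasks(phantomContours(spec), spec@imageSize,
                           spec@pixelSpacing)
  .labelCache[[key]] <- lab
  lab
}

#' Draw a random phantom subject specification
#'
#' Healthy subjects get a baseline T2 drawn from the healthy global
#' distribution (58.7 +/- 4.2 ms) and no lesions. Acute-myocarditis
#' subjects get a mildly elevated diffuse baseline (60.5 +/- 5 ms) plus one
#' to three focal lesions with T2 elevation 10--20 ms, angular extents
#' 40--130 degrees, subepicardial transmural fractions 0.5--1, spanning one
#' or two slice levels; the methods vignette motivates these choices.
#'
#' @param class "HV" or "ACM".
#' @param seed subject seed.
#' @param imageSize phantom image size (default 128).
#' @param ... further arguments to \code{\link{phantomSpec}}.
#' @return a \code{PhantomSpec}.
#' @export
sampleSubjectSpec <- function(class = c("HV", "ACM"), seed = 1,
                              imageSize = 128, ...) {
  class <- match.arg(class)
  withSeed(seed, {
    if (class == "HV") {
      base <- rnorm(1, 58.7, 4.2)
      lesions <- list()
    } else {
      base <- rnorm(1, 60.5, 5)
      nles <- sample(1:3, 1, prob = c(0.45, 0.35, 0.2))
      lesions <- lapply(seq_len(nles), function(i) {
        lv0 <- sample(1:3, 1)
        lvs <- lv0:min(3, lv0 + sample(0:1, 1))
        lesionSpec(slices = as.integer(outer(c(1, 2), (lvs - 1) * 2, "+")),
                   centerDeg = runif(1, 0, 360),
                   extentDeg = runif(1, 60, 160),
                   transmuralFraction = runif(1, 0.6, 1),
                   deltaT2 = runif(1, 10, 20))
      })
    }
    phantomSpec(imageSize = imageSize, baselineT2 = max(base, 30),
                lesions = lesions, seed = childSeed(seed, 97), ...)
  })
}

#' Simulate a phantom cohort through the image-level pipeline
#'
#' Generates \code{nHV + nACM} phantom subjects, fits a pixel-wise T2 map
#' for each, extracts AHA segment statistics and condenses them to
#' subject-level heterogeneity features. All randomness descends from one
#' master seed through per-subject child seeds.
#'
#' @param nHV,nACM subjects per class (defaults 30 and 31, the cohort sizes
#'   of the emulated study).
#' @param seed master seed.
#' @param fitMethod \code{"loglinear"} (default: fast, adequate at the
#'   phantom SNR) or \code{"rician_mle"}.
#' @param imageSize phantom image size (default 128).
#' @param returnTables also return the per-subject segment tables.
#' @param ... passed to \code{\link{sampleSubjectSpec}} and on to
#'   \code{\link{phantomSpec}}.
#' @return feature data.frame (one row per subject), or a list with
#'   \code{features} and \code{segmentTables} when \code{returnTables}.
#' @export
simulatePhantomCohort <- function(nHV = 30, nACM = 31, seed = 1,
                                  fitMethod = c("loglinear", "rician_mle"),
                                  imageSize = 128, returnTables = FALSE,
                                  ...) {
  fitMethod <- match.arg(fitMethod)
  classes <- c(rep("HV", nHV), rep("ACM", nACM))
  ids <- sprintf("%s%02d", classes, c(seq_len(nHV), seq_len(nACM)))
  feats <- vector("list", length(classes))
  tabs <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    spec <- sampleSubjectSpec(classes[i], seed = childSeed(seed, i),
                              imageSize = imageSize, ...)
    sub <- generatePhantomSubject(spec)
    map <- fitMap(sub$series, method = fitMethod)
    labels <- sub$truth@segmentLabels
    tab <- segmentStatistics(map, labels, subjectId = ids[i])
    feats[[i]] <- computeFeatures(tab, label = classes[i])
    if (returnTables) tabs[[i]] <- tab
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  if (returnTables) list(features = features, segmentTables = tabs)
  else features
}

#' Pipeline configuration
#'
#' Assembles (and completes with defaults) the configuration consumed by
#' \code{\link{runPipeline}}. Accepts a YAML file path or a list.
#'
#' @param config optional YAML path or list of overrides.
#' @param ... named overrides applied on top.
#' @return a complete configuration list.
#' @export
pipelineConfig <- function(config = NULL, ...) {
  defaults <- list(
    n_hv = 30, n_acm = 31, seed = 1, image_size = 128,
    fit_method = "loglinear", rule = "and",
    madsd_cut = 0.22, maxt2_cut = 68, cv_folds = 10, verbose = TRUE)
  if (is.character(config)) config <- yaml::read_yaml(config)
  user <- c(list(...), config)
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  stopifnot(defaults$seed == as.integer(defaults$seed))
  defaults
}

#' Run the full phantom-cohort analysis pipeline
#'
#' simulate -> fit -> segment -> features -> evaluate: simulates a phantom
#' cohort at image level, fits T2 maps, extracts segmental statistics and
#' heterogeneity features, then runs the group comparison, the combined
#' cut-off rule, logistic regression with ROC and stratified
#' cross-validation. All tabular artifacts and a JSON report are written to
#' \code{outDir}; the run is deterministic for a fixed seed.
#'
#' @param config a \code{\link{pipelineConfig}} (or YAML path / list).
#' @param outDir output directory.
#' @return the report, invisibly (also written as \code{report.json}).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("t2run")) {
  cfg <- pipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  stages <- character()

  say("[simulate/fit/segment/features] %d HV + %d ACM phantoms (seed %d)",
      cfg$n_hv, cfg$n_acm, cfg$seed)
  sim <- simulatePhantomCohort(cfg$n_hv, cfg$n_acm, seed = cfg$seed,
                               fitMethod = cfg$fit_method,
                               imageSize = cfg$image_size,
                               returnTables = TRUE)
  stages <- c(stages, "simulate", "fit", "segment", "features")
  features <- sim$features
  writeFeatures(features, file.path(outDir, "features.csv"))
  writeSegmentTable(do.call(rbind, sim$segmentTables),
                    file.path(outDir, "segments.csv"))

  say("[evaluate] group comparison, cut-off rule, logistic model")
  comparison <- compareGroups(features)
  write.csv(comparison, file.path(outDir, "comparison.csv"),
            row.names = FALSE)
  predicted <- applyCutoffRule(features, cfg$madsd_cut, cfg$maxt2_cut,
                               rule = cfg$rule)
  write.csv(data.frame(subject_id = features$subject_id,
                       label = features$label, predicted = predicted),
            file.path(outDir, "classification.csv"), row.names = FALSE)
  perf <- classificationPerformance(predicted, features$label)

  results <- list(n_subjects = nrow(features), cutoff_rule = perf)
  nMin <- min(table(features$label))
  if (nMin >= 5) {
    lm2 <- fitLogistic(features[, c("maxT2", "madSD")], features$label)
    prob <- predictLogistic(lm2, features)
    roc <- rocCurve(prob, features$label)
    kcv <- min(cfg$cv_folds, nMin)
    cv <- crossValidate(features[, c("maxT2", "madSD")], features$label,
                        fitFun = fitLogistic,
                        predictFun = function(m, X)
                          ifelse(predictLogistic(m, X) > 0.5, "ACM", "HV"),
                        k = kcv, seed = cfg$seed)
    results$logistic <- list(
      intercept = lm2$intercept, coefficients = as.list(lm2$coefficients),
      auc = roc$auc, cv_accuracy = cv$accuracy, cv_folds = kcv)
  }
  stages <- c(stages, "evaluate")

  report <- list(
    package = "myoT2map",
    version = as.character(utils::packageVersion("myoT2map")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, parameters = cfg[setdiff(names(cfg), "verbose")],
    stages = stages, subjects = features$subject_id, results = results)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] report written to %s", file.path(outDir, "report.json"))
  invisible(report)
}
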