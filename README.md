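# myoT2map

Quantitative myocardial edema imaging by multi-echo T2 mapping, for
researchers working on cardiovascular MR tissue characterization in acute
myocarditis (ACM).

Absolute myocardial T2 varies so much between subjects and sequences that a
single global cut-off separates health from disease poorly — and
myocarditis is often focal, so averaging washes lesions out. This package
implements an analysis built on *tissue inhomogeneity* instead:

* pixel-wise mono-exponential T2 fitting of multi-echo GraSE-style
  magnitude series, by log-linear least squares and by **maximum likelihood
  under a Rician noise model**,
  `ℓ = Σᵢ log Mᵢ − 2 log σ − (Mᵢ² + νᵢ²)/(2σ²) + log I₀(Mᵢνᵢ/σ²)` with
  `νᵢ = A·exp(−TEᵢ/T2)`;
* **AHA 16-segment** segmentation (6 basal / 6 mid / 4 apical sectors from
  endo/epicardial contours and the RV-insertion angle), recording per
  segment the mean T2 and the within-segment pixel standard deviation
  ("pixel-SD");
* the subject-level heterogeneity features
  **maxT2, maxSD** (highest segmental value) and
  **madT2, madSD** (mean absolute deviation across segments,
  `madSD = Σⱼ|yⱼ − ȳ|/k` with `yⱼ = ln(pixel-SDⱼ)`);
* the diagnostic layer: the combined cut-off rule
  (**ACM iff madSD > 0.22 and maxT2 > 68 ms**), logistic regression with
  odds factors, Gini classification trees, random-forest importance,
  stratified cross-validation, ROC/AUC, and the conventional
  reference-range (mean + k·SD) baseline;
* a first-class synthetic-data generator — annular short-axis phantoms
  with wedge-shaped subepicardial lesions and Rician noise, plus a
  feature-level cohort sampler — so the whole chain is testable without
  patient data.

See the methods vignette (`vignettes/t2-heterogeneity-mapping.Rmd`) for the
models, parameter choices and limitations.

## Worked example

Simulate one subject with a focal mid-ventricular lesion (+15 ms over an
80° wedge), fit the T2 map, extract segment statistics and classify:

```r
library(myoT2map)

spec <- phantomSpec(seed = 7, lesions = list(
  lesionSpec(slices = 3:4, centerDeg = 45, extentDeg = 80,
             transmuralFraction = 0.8, deltaT2 = 15)))
sub <- generatePhantomSubject(spec)
sub$series
#> EchoSeries: 128 x 128 pixels, 6 slices, 9 echoes
#>   TE (ms): 15, 22.7, 30.4, 38.1, 45.8, 53.5, 61.2, 68.9, 76.6
#>   masked pixels: 2808

map <- fitMap(sub$series, method = "loglinear")
tab <- segmentStatistics(map, sub$truth@segmentLabels, subjectId = "demo")
head(tab[order(-tab$mean_T2_ms), ], 2)
#>    subject_id segment_id mean_T2_ms pixel_SD_ms n_pixels  level flagged
#> 12       demo         12   85.28632   15.397127      156    mid   FALSE
#> 13       demo         13   74.90935    6.938439      234 apical   FALSE

feat <- computeFeatures(tab, label = "unknown")
feat[, c("globalT2", "globalSD", "maxT2", "maxSD", "madT2", "madSD")]
#>   globalT2 globalSD    maxT2    maxSD    madT2    madSD
#> 1 62.61027 8.690245 85.28632 15.87948 8.372011 0.254374

applyCutoffRule(feat)
#> [1] "ACM"
```

The lesion straddles segment 12 and its neighbours: that segment's mean T2
(85.3 ms) and pixel-SD (15.4 ms) are elevated, which drives maxT2 above
68 ms and madSD above 0.22 — so the combined rule calls the subject ACM.
The global mean (62.6 ms) alone would sit inside the healthy range.

The reference logistic model turns coefficients into odds statements:

```r
oddsFactor(referenceLogisticModel(), "madSD", 0.1)
#> [1] 7.644604   # +0.1 madSD multiplies the ACM odds ~7.6-fold
```

A full cohort analysis (simulate → fit → segment → features → evaluate,
with all artifacts and a JSON report):

```r
report <- runPipeline(pipelineConfig(list(n_hv = 30, n_acm = 31, seed = 1)),
                      outDir = "t2run")
```

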