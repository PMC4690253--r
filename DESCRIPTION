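Package: myoT2map
Title: Quantitative Myocardial T2 Mapping and Tissue-Heterogeneity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantitative myocardial edema imaging by multi-echo
    T2 relaxometry. Simulates cardiac short-axis gradient-spin-echo (GraSE)
    magnitude image series with focal inflammatory lesions, fits pixel-wise
    mono-exponential T2 maps by log-linear least squares and by maximum
    likelihood under a Rician noise model, segments the left-ventricular
    myocardium according to the AHA 16-segment model, and derives
    subject-level tissue-heterogeneity statistics (maxT2, maxSD, madT2,
    madSD) from segmental means and pixel standard deviations. Includes the
    downstream diagnostic layer: Welch and Wilcoxon group comparisons with
    effect sizes, a combined cut-off rule, logistic regression, Gini
    classification trees, random-forest variable importance, stratified
    cross-validation, ROC analysis, and a reference-range (mean + k*SD)
    baseline classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    RNifti,
    jsonlite,
    pracma,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    pROC
Config/testthat/edition: 3
biocViews: Software, Visualization, Classification, StatisticalMethod
RoxygenNote: 7.3.3
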