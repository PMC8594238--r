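Package: octairis
Title: Quantification of Iris and Retinal Perfusion from OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of en-face optical coherence tomography
    angiography (OCTA) of the iris and macula. Provides seeded synthetic
    angiogram phantoms with vessel ground truth, Otsu and adaptive vessel
    binarization, topology-preserving skeletonization, the pupil-margin
    region-of-interest scheme at the 9 o'clock meridian with nested
    one-third, two-thirds and full segments, vessel area density (VAD) and
    vessel skeleton density (VSD) with replicate averaging, cohort
    simulation, and the group-comparison statistics (Lilliefors normality,
    Levene, independent t-test, one-way ANOVA with pairwise contrasts,
    chi-square, exact noncentral-t sample size) used to study iris
    perfusion in ischemic retinal disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    car,
    nortest,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
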