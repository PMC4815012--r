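Package: musclescreen
Title: Fluorescence Biosensor Quantification and Dose-Response Analysis for
    Muscle Hyperactivity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for a zebrafish muscle-hyperactivity
    fluorescence reporter screen: semi-automatic quantification of GFP reporter
    intensity from embryo trunk micrographs (grayscale conversion, Gaussian
    smoothing, disc region-of-interest extraction, global intensity
    statistics), fold-induction normalisation against solvent controls, an
    ANOVA-gated Gaussian-in-log-concentration (peaked) concentration-response
    model with closed-form EC1.5 inversion and a linear-model fallback, Tukey
    HSD and Welch t group comparisons, and spike height/interval analysis of
    GCaMP muscle calcium traces. Includes a ground-truthed synthetic data
    generator (embryo images, dose series, calcium traces) so every stage is
    testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    tiff,
    png,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
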