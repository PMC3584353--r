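Package: stainmix
Title: Mixture-Model Classification of Immunostaining Intensity with Song
    Stereotypy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies per-nucleus immunostaining intensity in grayscale
    histology fields, separates weakly- from intensely-stained nuclear
    populations per animal with univariate Gaussian mixtures fitted by EM and
    selected by BIC, using the peak of classification uncertainty as the
    cutoff between classes. Computes class densities, their exponential
    one-phase decay with age, birdsong syntax stereotypy statistics
    (linearity, consistency, motif similarity), and the associated inference
    layer (nonlinear decay fits, ANOVA with Tukey letter displays, Fisher's
    exact tests). Includes a seeded synthetic-cohort generator producing
    rendered histology fields, song corpora and label-colocalization tables
    with known ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    mclust,
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
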