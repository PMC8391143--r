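Package: voxelencode
Title: Voxel-Wise Visual Encoding Models with Sparse Regression and
    Representational Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates voxel-wise encoding models of visual
    cortex. Hierarchical stimulus features (one matrix per network layer)
    are reduced by principal component analysis and mapped to single-voxel
    fMRI responses by regularized orthogonal matching pursuit (ROMP), a
    greedy sparse regression.  Prediction accuracy is the Pearson
    correlation between measured and predicted validation responses;
    significance comes from a randomization test, model comparisons from a
    sign-flip permutation test, and attainable accuracy from Monte-Carlo
    noise ceilings estimated from repeated validation runs.
    Representational similarity analysis (correlation-distance RDMs
    compared with Kendall's tau-a) complements the voxel-wise view.  A
    seeded synthetic-study generator with known ground truth (nested ReLU
    feature cascades, sparse voxel readouts, ROI-specific layer
    preferences, repeated noisy runs) exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
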