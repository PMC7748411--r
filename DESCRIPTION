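Package: comboscape
Title: Interaction Profile Classification and Landscapes for Combination-Treatment Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse factorial combination-treatment expression
    experiments (control, stimulus X, stimulus Y, combination X+Y). Provides a
    complete taxonomy of 123 qualitatively distinct interaction profiles
    represented as linear sign-relation systems, a polytope sampler that
    generates calibrated synthetic training data, a simulation-trained
    probabilistic Random Forest classifier (with LDA and deterministic-matching
    baselines), Bliss-index interaction scoring, per-dataset analysis pipelines,
    multi-dataset landscape integration, and constrained gene-set
    over-representation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
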