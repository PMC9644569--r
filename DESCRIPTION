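Package: tmedeconv
Title: Hierarchical Reference-Based Deconvolution of the Tumor
    Microenvironment from DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-type-specific, six-layer hierarchical reference-based
    deconvolution of tumor-microenvironment cell composition from Infinium
    DNA methylation beta values. Builds the twelve-layer-library bundle from
    tumor/normal training data and purified-cell reference panels (informative
    differentially methylated CpG selection, kernel-density tumor purity,
    empirical-Bayes moderated marker ranking), projects bulk mixtures onto
    library class means by constrained-projection quadratic programming, and
    cascades per-layer relative fractions into absolute proportions for up to
    seventeen cell classes. Includes seeded synthetic-data generators with
    known ground truth and recovery metrics (signed and absolute percent
    error, RMSE, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
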