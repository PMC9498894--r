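Package: motifconv
Title: Multinomial Convolutional Networks for Sequence-Activity Modeling
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Regression modeling of DNA sequence activity (for example
    massively parallel reporter assay readouts) with convolutional networks
    whose first-layer kernels are constrained, through a temperature
    softmax, to be multinomial distributions over the four nucleotides.
    Each kernel is therefore directly interpretable as a position weight
    matrix, scores sequences by background-corrected log-likelihood
    ratios, and can be exported in MEME minimal format for downstream
    motif-database searches. Includes ten-fold cross-validation with
    Spearman scoring, a conventional CNN baseline, information-content
    analytics with a Welch test against reference motif sets, a synthetic
    MPRA-style data generator with planted activator and repressor
    motifs, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
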