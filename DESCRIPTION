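Package: dcnet
Title: Differential Gene Coexpression Networks with KS-Optimal Thresholding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-group gene coexpression network analysis. Computes per-group
    absolute Pearson coexpression levels for all gene pairs, selects the
    disease-associated coexpression threshold by maximizing the deviation
    between the groups' inverted empirical distribution functions (two-sample
    Kolmogorov-Smirnov statistic), verifies the strong/weak dichotomy by an
    uncorrected chi-square test, partitions strongly coexpressed pairs into
    common, normal-specific and disease-specific networks with edge
    thicknesses mapped linearly to 1-6 and Pajek export, and enumerates
    miRNA/transcription-factor regulatory signatures (MRS/TRS and their
    composite, CRS) over the resulting networks. Ships a synthetic expression
    generator with planted per-group correlation blocks so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
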