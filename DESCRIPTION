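Package: phosdia
Title: Quantitative DIA Phosphoproteomics Analysis with Permutation-FDR
    Differential Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-acquisition analysis of two-condition data-independent
    acquisition (DIA/SWATH) phosphoproteomics experiments: local-regression
    normalization, log2 transform, valid-value filtering, downshifted-normal
    imputation of missing intensities, SAM-style S0-moderated two-sided
    t-testing with permutation-based false discovery rate control,
    discrimination of differential phosphorylation from protein-abundance
    change by total-proteome normalization, phosphosite classification with
    kinase-motif matching, and Fisher's exact pathway enrichment with
    enrichment factors. Includes a synthetic-data generator that emulates
    the statistical structure of a two-condition phosphoproteome experiment
    (log-normal intensities, intensity-dependent missingness, ground-truth
    phospho- and abundance-driven effects) so every stage can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
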