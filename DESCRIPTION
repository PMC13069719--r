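Package: methvar
Title: Cataloguing Variable and Stable DNA Methylation in Whole Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building a catalogue of interindividually variable
    (VMP) and stable (SMP) CpG probes from Illumina EPIC-style beta-value
    matrices, using repeated downsampling with per-probe standard-deviation
    deciles and discovery/validation intersection.  Includes cell-composition
    correction by per-probe linear models, genomic-context enrichment against
    the array background, methylation-QTL cis/trans annotation with
    TAD/chromatin-loop co-occupancy, a from-scratch Hartigan dip test for
    bimodality-based epiallele screening, and correlation of methylation
    variability with gene-expression variability.  A synthetic-data module
    generates EPIC-array-like bundles with planted probe classes so every
    stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    yaml,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
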