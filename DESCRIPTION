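Package: dgepair
Title: Exact Differential Expression Analysis for Two Sequencing Libraries
Version: 1.0.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Digital gene expression analysis for a pair of tag-count
    sequencing libraries, as used in early de novo transcriptome studies
    without biological replicates. Implements RPKM quantification, the
    Audic-Claverie exact test for equal expression between two libraries
    of unequal depth, Benjamini-Hochberg false discovery rate control,
    differential-gene calling by joint FDR and fold-change thresholds,
    hypergeometric term (GO/pathway) over-representation analysis, and
    homology-based candidate gene screening. Ships a two-library count
    simulator with known ground truth so that every pipeline stage is
    testable without raw read data, and a reproducible end-to-end
    pipeline driver with a run manifest.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
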