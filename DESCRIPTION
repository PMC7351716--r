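Package: catchRelease
Title: Design and Evaluation of Sequence-Selective DNA Catch-and-Release
    Pulldowns
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for hybridization-capture pulldowns that use
    polymer-grafted anchor strands and three-domain catcher probes with
    toehold-mediated strand-displacement (TMSD) release. Designs catcher
    strand libraries that tile target transcripts with alternating
    sense/antisense binding sites, screens them for off-target capture by
    exact shared-substring search, simulates the stochastic dual-selection
    catch-and-release process, evaluates targeted cDNA depletion from
    per-base coverage tracks and TPM expression tables, and implements the
    flow-fractionation conformation and anchor-capacity calculations used
    to characterize the polymer carrier. Seeded synthetic-data generators
    make every step testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Transcriptomics, Coverage, Software
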