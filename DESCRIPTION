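Package: grnx
Title: Cross-Species Meta-Analysis of Transcription-Factor Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates many differential-expression and ChIP peak data sets
    per species into per-gene confidence scores for transcription-factor
    (p53/DREAM) regulation, calls direct and indirect target genes, compares
    one-to-one orthologs between two species, classifies regulatory
    divergence, and quantifies binding-site turnover, response-element motif
    content and genomic-feature enrichment. Ships a fully seeded two-species
    synthetic-data generator with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
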