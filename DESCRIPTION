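Package: apa3seq
Title: Alternative Polyadenylation Analysis from 3' End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls cleavage and polyadenylation sites from aligned 3'-end
    sequencing reads (QuantSeq REV style protocols), removes internal-priming
    (mis-priming) artifacts by a genomic A-content rule, filters sites by
    replicate reproducibility, and tests differential polyA-site usage between
    conditions with a polyA usage index (PUI). Classifies cryptic polyA sites
    activated upon perturbation by genomic region (premature, 3'UTR-internal,
    downstream of the annotated gene end), couples them with cryptic splice
    junctions, scores site strength from the surrounding sequence, and
    computes a targeted 3'UTR-lengthening index from RNA-seq coverage. A
    synthetic-data module simulates a small genome with multi-polyA-site
    genes, condition-dependent usage shifts and internal-priming artifacts so
    the whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
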