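Package: nadcall
Title: Calling and Characterizing Nucleolus-Associated Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies nucleolus-associated domains (NADs) from binned
    nucleolar versus whole-cell DNA sequencing counts using a normalized
    two-fold enrichment rule, annotates the genes they contain (NAGs),
    compares NAD and NAG repertoires across cell lines, integrates ATAC,
    H3K4me3 and RNA polymerase II peak sets into a promoter-level
    transcriptional-activity classification, and quantifies nucleolar
    enrichment of transcripts from nucleolar versus total RNA profiling.
    Includes a seeded synthetic-data generator (genome, genes, planted
    NADs, negative-binomial bin counts, promoter peak sets and
    compartmentalized expression) so that every stage of the pipeline can
    be exercised and validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    methods,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
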