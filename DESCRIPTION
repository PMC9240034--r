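Package: meriptools
Title: MeRIP-Seq Peak Calling, m6A Landscape Profiling, and RNA
    Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sliding-window peak calling for m6A-seq (MeRIP-seq) on the
    longest isoform of each gene with low-count window exclusion,
    IP-versus-input Fisher enrichment testing and Benjamini-Hochberg FDR
    control; metagene and transcript-segment landscape profiling with a
    DRACH motif enrichment test; knockout-versus-wild-type differential
    methylation; actinomycin-D decay time-course normalization,
    log-linear half-life fitting and genotype stability comparison;
    delta-delta-Ct relative quantification; TPM quantification with a
    documented Welch-t differential-expression stand-in, threshold-based
    DEG classification and hypergeometric gene-set enrichment. A
    synthetic-data generator plants DRACH methylation sites, genotype
    effects, decay rates and expression changes with known ground truth
    so every stage is verifiable by parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
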