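Package: flankpref
Title: Flanking-Sequence Preference Analysis for DNA Methyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the flanking-sequence preferences of DNA
    methyltransferases from deep-enzymology experiments and for relating them
    to genomic methylation patterns. Implements hairpin-bisulfite read
    simulation and processing (trimming, quality filtering, deduplication,
    strand-pair reconstitution, central-site methylation calling with CCWGG
    exclusion), per-position observed/expected base enrichment profiles of
    methylated product pools, fitting of 256 NNCGNN methylation rate constants
    to monoexponential reaction progress curves on a shared latent (virtual)
    time axis, correlation of biochemical preferences with whole-genome
    bisulfite methylomes including a sliding-window local-correlation
    randomization Z-test, and composition-normalized CpG and CCCG/CGGG
    enrichment scanning of retrotransposon consensus sequences. A synthetic
    data module generates reads, methylomes and repeat-like sequences with
    known ground truth so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
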