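Package: haplocall
Title: Haplotype-Aware SNP and Indel Calling from Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls SNPs and small indels from long-read alignments using
    long-range haplotype structure. SNP candidates are encoded as pileup
    count tensors over distant likely-heterozygous sites sharing reads with
    the candidate and classified by a small convolutional network; reads are
    then phased from the SNP calls and indels are called per haplotype from
    multiple-sequence-alignment frequency tensors with consensus-based
    allele inference. Includes a deterministic diploid read simulator, a
    variant comparator with precision/recall/F1 reporting, and a
    command-line pipeline covering SNP-only, phased-SNP, indel-only and
    combined modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Matrix,
    Rsamtools,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    S4Vectors,
    VariantAnnotation,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
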