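Package: mmseqtools
Title: Joint Mutation and Methylation Co-Detection Sequencing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for duplex UMI-based co-detection of DNA
    mutations and methylation from a single sequencing library. Read pairs
    are demultiplexed into a genetic stream (MM-genet, protected copy
    strands with intact UMIs) and a methylation stream (MM-meth, converted
    original strands with C-to-T/G-to-A collapsed UMIs). Provides
    conversion-aware UMI pool management, per-CpG methylation calling with
    spike-in conversion QC, UMI-aware duplicate removal and consensus
    variant calling, binned copy-number detection, duplex phasing for
    allele-specific methylation, clinical decision layers (ctDNA calling,
    immune cell-free DNA deconvolution, biallelic-loss classification,
    greedy panel design, qPCR call rules), and an in-silico library
    simulator that exercises every stage against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, DNAMethylation, Epigenetics, CopyNumberVariation,
    VariantDetection, QualityControl
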