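Package: snptransmit
Title: DNA-to-RNA SNP Transmission Analysis for Allopolyploid Subgenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches homozygous single-nucleotide polymorphisms between DNA and
    RNA variant call sets (and between a parent and offspring line), computes
    per-gene transmission ratios, quantifies subgenome asymmetry in
    allopolyploids such as Brassica napus (An vs Cn), and fits binned linear
    regressions between gene expression (TPM) and SNP counts or transmission
    ratios. Includes GATK-style hard filtering (quality expression and SNP
    cluster rules), a codon-level SNP consequence classifier against a GFF3
    annotation, SNP density and window-scan summaries, syntenic-pair t-tests,
    and a synthetic-data generator that emits FASTA/GFF3/VCF/TPM inputs with
    planted transmission structure so every stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
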