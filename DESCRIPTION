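Package: hervtrace
Title: Tracing Immunopeptidomic Peptides to Endogenous Retrovirus Genomic Origins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Traces short query peptides (for example MHC-presented peptides from
    immunopeptidomics) to candidate human endogenous retrovirus (HERV) genomic
    origins. Builds a deduplicated six-frame open-reading-frame (ORF) protein
    database and a matching genomic-coordinate database from a provirus
    reference, optionally personalized with per-sample single-nucleotide
    variants; searches peptides against the ORFs with an exact 100%-identity
    full-length criterion; back-maps hits to genomic fragments of exactly three
    times the peptide length; quantifies per-sample RNA-seq read support over
    the fragments with featureCounts-style semantics including fractional
    multi-map counting; and reports the most expressed candidate origin per
    peptide at cohort and sample level, with validation-ready DNA sequence
    contexts and heatmaps. A deterministic synthetic-data generator plants
    ground-truth peptides, reads and variants in a toy genome so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Rsamtools,
    vcfR,
    pheatmap,
    jsonlite,
    parallel,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
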