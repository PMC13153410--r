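# Hand-built single-contig alignments: reads is a data.frame with columns
# qname, flag, pos, nh (and optionally mapq).
write_test_bam <- function(dir, name, reads, contig_len = 5000L,
                           read_len = 50L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:chrT\tLN:%d", contig_len))
  recs <- character(0)
  if (nrow(reads) > 0) {
    if (is.null(reads$mapq)) reads$mapq <- 50L
    reads <- reads[order(reads$pos), , drop = FALSE]
    recs <- sprintf("%s\t%d\tchrT\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
                    reads$qname, reads$flag, reads$pos, reads$mapq,
                    read_len, strrep("A", read_len), strrep("I", read_len),
                    reads$nh)
  }
  sam <- file.path(dir, paste0(name, ".sam"))
  writeLines(c(hdr, recs), sam)
  Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                   indexDestination = TRUE)
  file.path(dir, paste0(name, ".bam"))
}

toy_fragments <- function(starts, ends, peptide_id = "p") {
  n <- length(starts)
  data.frame(peptide_id = rep(peptide_id, length.out = n),
             peptide = "AVLLPQPPK", chrom = "chrT",
             start = starts, end = ends, strand = "+",
             fragment_id = sprintf("chrT:%d-%d(+)", starts, ends),
             n_sources = 1L, region_ids = "r", orf_ids = "o",
             orf_spans = "chrT:1-5000", provenance = "reference",
             stringsAsFactors = FALSE)
}
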