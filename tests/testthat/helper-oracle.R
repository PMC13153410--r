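# Independent brute-force oracles, deliberately built on base R only (no
# Biostrings) so they share no code path with the implementation they check.

# Standard genetic code, bases enumerated T,C,A,G (the classic 64-codon
# ordering), written down independently of any package table.
oracle_code <- local({
  aas <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  bases <- c("T", "C", "A", "G")
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]), collapse = "")
}

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(dna, 3L * i - 2L, 3L * i)
    out[i] <- if (grepl("N", codon)) "X" else oracle_code[[codon]]
  }
  paste(out, collapse = "")
}

oracle_six_frames <- function(dna) {
  rc <- oracle_revcomp(dna)
  list("+1" = oracle_translate(dna),
       "+2" = oracle_translate(substring(dna, 2)),
       "+3" = oracle_translate(substring(dna, 3)),
       "-1" = oracle_translate(rc),
       "-2" = oracle_translate(substring(rc, 2)),
       "-3" = oracle_translate(substring(rc, 3)))
}

# All peptide occurrences inside stop-free stretches of all six frame
# translations of every region sequence. Keys: "region_id|frame|aa_offset"
# (offset within the whole frame translation). Precomputed per-region frame
# translations can be passed to amortize the scan over many peptides.
oracle_scan_keys <- function(regions, peptide, frames_list = NULL) {
  keys <- character(0)
  for (i in seq_len(nrow(regions))) {
    frames <- if (is.null(frames_list)) {
      oracle_six_frames(regions$sequence[i])
    } else frames_list[[i]]
    for (f in names(frames)) {
      tr <- frames[[f]]
      pieces <- strsplit(tr, "*", fixed = TRUE)[[1]]
      off <- 0L
      for (p in pieces) {
        j <- 1L
        repeat {
          hit <- regexpr(peptide, substring(p, j), fixed = TRUE)
          if (hit == -1L) break
          pos <- j + as.integer(hit) - 1L
          keys <- c(keys, paste(regions$region_id[i], f, off + pos - 1L,
                                sep = "|"))
          j <- pos + 1L
        }
        off <- off + nchar(p) + 1L
      }
    }
  }
  sort(keys)
}

# Implementation-side keys comparable to oracle_scan_keys: expand each hit
# over its ORF's placements (each placement knows its frame and the ORF's
# offset within that frame).
impl_hit_keys <- function(hits, db) {
  if (nrow(hits) == 0L) return(character(0))
  keys <- character(0)
  for (i in seq_len(nrow(hits))) {
    pl <- db$placements[db$placements$orf_id == hits$orf_id[i], , drop = FALSE]
    rid <- db$orfs$region_id[match(hits$orf_id[i], db$orfs$orf_id)]
    keys <- c(keys, paste(rid, pl$frame,
                          pl$frame_offset + hits$protein_offset[i],
                          sep = "|"))
  }
  sort(keys)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# A small in-memory region table (no files needed).
make_test_regions <- function(seqs, chrom = "chrT", start = 1001L,
                              strand = "+", assembly = "test") {
  n <- length(seqs)
  starts <- integer(n)
  s <- start
  for (i in seq_len(n)) {
    starts[i] <- s
    s <- s + nchar(seqs[i]) + 500L
  }
  regions <- data.frame(
    region_id = sprintf("tr%02d", seq_len(n)),
    chrom = chrom, start = starts,
    end = starts + nchar(seqs) - 1L,
    strand = rep(strand, length.out = n),
    sequence = toupper(seqs), assembly = assembly,
    stringsAsFactors = FALSE)
  class(regions) <- c("herv_regions", "data.frame")
  regions
}

# Shared fixture cohort, built once per test run.
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture_cohort(file.path(tempdir(), "hervtrace-fixture"),
                                    seed = 42L)
    }
    cache
  }
})

case_study_table <- function() {
  utils::read.delim(system.file("extdata", "case_study_fragments.tsv",
                                package = "hervtrace"),
                    stringsAsFactors = FALSE)
}
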