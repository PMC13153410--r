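db_with_protein <- function(...) {
  # build a database whose first region encodes the given peptides in frame
  units <- vapply(list(...), function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(aa) {
      names(oracle_code)[oracle_code == aa][1]
    }, character(1)), collapse = "")
  }, character(1))
  seqs <- paste0(paste(units, collapse = "TAA"), "TAA")
  build_database(make_test_regions(seqs, start = 101L))
}

test_that("exact search finds every occurrence and nothing else", {
  db <- db_with_protein("AVLLPQPPK")
  peps <- data.frame(peptide_id = c("hit", "miss"),
                     sequence = c("AVLLPQPPK", "AVLLPQPPR"),
                     stringsAsFactors = FALSE)
  hits <- find_peptide_hits(peps, db)
  expect_equal(unique(hits$peptide_id), "hit")
  expect_true(all(hits$identity_pct == 100))
  expect_true(all(hits$align_len == 9L))
  # substring invariant
  prot <- db$orfs$protein[match(hits$orf_id, db$orfs$orf_id)]
  expect_true(all(substr(prot, hits$protein_offset + 1L,
                         hits$protein_offset + 9L) == "AVLLPQPPK"))
})

test_that("a peptide occurring twice in one ORF yields two offsets", {
  db <- db_with_protein("GAVLLPQPPKAVLLPQPPKG")
  peps <- data.frame(peptide_id = "p", sequence = "AVLLPQPPK",
                     stringsAsFactors = FALSE)
  hits <- find_peptide_hits(peps, db)
  orf <- db$orfs$protein[match(hits$orf_id, db$orfs$orf_id)]
  two <- hits[orf == "GAVLLPQPPKAVLLPQPPKG", ]
  expect_equal(sort(two$protein_offset), c(1L, 10L))
})

test_that("invalid peptides and empty databases are rejected", {
  db <- db_with_protein("AVLLPQPPK")
  expect_error(find_peptide_hits(
    data.frame(peptide_id = "x", sequence = "AV*LP"), db), "Invalid")
  expect_error(find_peptide_hits(
    data.frame(peptide_id = "x", sequence = "AK"), db), "Invalid")
  empty <- db
  empty$orfs <- empty$orfs[0, ]
  expect_error(find_peptide_hits(
    data.frame(peptide_id = "x", sequence = "AVLLPQPPK"), empty), "Empty")
})

test_that("exact search equals the brute-force six-frame oracle on random data", {
  set.seed(404)
  for (rep in 1:3) {
    regions <- make_test_regions(
      vapply(1:2, function(i) random_dna_str(400L), character(1)),
      strand = sample(c("+", "-"), 2, replace = TRUE))
    db <- build_database(regions)
    proteins <- db$orfs$protein[nchar(db$orfs$protein) >= 12L]
    for (k in 1:10) {
      pep <- if (k %% 2 == 0 && length(proteins) > 0) {
        p <- sample(proteins, 1)
        len <- sample(9:min(12, nchar(p)), 1)
        start <- sample(nchar(p) - len + 1L, 1)
        substr(p, start, start + len - 1L)
      } else random_peptide(sample(9:15, 1))
      if (grepl("X", pep)) next
      hits <- find_peptide_hits(
        data.frame(peptide_id = "q", sequence = pep), db)
      expect_equal(impl_hit_keys(hits, db), oracle_scan_keys(regions, pep),
                   info = pep)
    }
  }
})

test_that("hits never disappear when the database grows", {
  dbA <- db_with_protein("AVLLPQPPK")
  dbB <- db_with_protein("AVLLPQPPK", "NEAIEQVRAICLRAW")
  peps <- data.frame(peptide_id = "p", sequence = "AVLLPQPPK",
                     stringsAsFactors = FALSE)
  keyA <- impl_hit_keys(find_peptide_hits(peps, dbA), dbA)
  keyB <- impl_hit_keys(find_peptide_hits(peps, dbB), dbB)
  expect_true(all(keyA %in% keyB))
})

test_that("blastp backend is a filtered subset of (here: equal to) exact search", {
  fx <- fixture_cohort()
  regions <- load_reference(fx$regions_fa, fx$regions_bed, assembly = "toy")
  db <- build_database(regions)
  peps <- read_peptides(fx$peptides_fa)
  exact <- find_peptide_hits(peps, db)
  blast <- find_peptide_hits(peps, db, query_config(backend = "blastp"))
  key <- function(h, d) paste(h$peptide_id, h$orf_id, h$protein_offset)
  expect_true(all(key(blast) %in% key(exact)))
  expect_true(all(blast$identity_pct == 100))
  expect_true(all(blast$align_len == nchar(blast$peptide)))
})

test_that("fragment arithmetic reproduces the span law on both strands", {
  fx <- fixture_cohort()
  regions <- load_reference(fx$regions_fa, fx$regions_bed, assembly = "toy")
  db <- build_database(regions)
  peps <- read_peptides(fx$peptides_fa)
  frags <- hit_to_fragment(find_peptide_hits(peps, db), db)
  expect_gt(nrow(frags), 0L)
  expect_equal(frags$end - frags$start + 1L, 3L * nchar(frags$peptide))
  expect_true(all(frags$start >= frags$orf_start &
                    frags$end <= frags$orf_end))
  # offset-0 hit on a '+' placement starts at the placement start
  off0 <- frags[frags$protein_offset == 0L & frags$strand == "+", ]
  expect_true(all(off0$start == off0$orf_start))
})

test_that("fragment merging unions sources deterministically", {
  # two regions with identical sequence place the same protein at two loci,
  # but identical genomic windows only arise from one locus, so merge on a
  # hand-built table instead
  f <- data.frame(peptide_id = "p", peptide = "AVLLPQPPK", chrom = "chrT",
                  start = c(100L, 100L, 400L), end = c(126L, 126L, 426L),
                  strand = "+", region_id = c("r1", "r2", "r1"),
                  orf_id = c("o1", "o2", "o3"), protein_offset = 0L,
                  orf_start = c(100L, 91L, 400L),
                  orf_end = c(126L, 135L, 426L), provenance = "reference",
                  stringsAsFactors = FALSE)
  m <- merge_fragments(f)
  expect_equal(nrow(m), 2L)
  expect_equal(m$n_sources, c(2L, 1L))
  expect_equal(m$orf_ids[1], "o1,o2")
  expect_equal(merge_fragments(f[0, ]), m[0, ], ignore_attr = TRUE)
  # deterministic order by (peptide, chrom, start)
  expect_true(!is.unsorted(m$start))
})

test_that("GTF round-trips through write and read, and parses externally", {
  fx <- fixture_cohort()
  regions <- load_reference(fx$regions_fa, fx$regions_bed, assembly = "toy")
  db <- build_database(regions)
  peps <- read_peptides(fx$peptides_fa)
  frags <- merge_fragments(hit_to_fragment(find_peptide_hits(peps, db), db))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(frags, gtf)
  lines <- readLines(gtf)
  expect_equal(length(lines), nrow(frags))
  expect_true(all(lengths(strsplit(lines, "\t")) == 9L))
  back <- read_gtf(gtf)
  expect_equal(back, frags)
  # minus-strand features keep start < end with strand in column 7
  minus <- strsplit(lines[frags$strand == "-"][1], "\t")[[1]]
  expect_equal(minus[7], "-")
  expect_lt(as.integer(minus[4]), as.integer(minus[5]))
  # a standard GTF reader agrees on coordinates and attributes
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(gtf)
  expect_equal(length(gr), nrow(frags))
  expect_equal(GenomicRanges::start(gr), frags$start)
  expect_equal(as.character(S4Vectors::mcols(gr)$peptide_id),
               frags$peptide_id)
})

test_that("peptide FASTQ input is accepted with qualities ignored", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@pep1", "AVLLPQPPK", "+", "IIIIIIIII"), fq)
  p <- read_peptides(fq)
  expect_equal(p$sequence, "AVLLPQPPK")
})
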