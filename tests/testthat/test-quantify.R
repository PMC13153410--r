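test_that("unique reads inside a fragment are counted once each", {
  dir <- withr::local_tempdir()
  frag <- toy_fragments(1000L, 1026L)
  reads <- data.frame(qname = sprintf("r%d", 1:6),
                      flag = 0L,
                      pos = c(1000L, 1001L, 1002L, 990L, 1010L, 2000L),
                      nh = 1L, stringsAsFactors = FALSE)
  bam <- write_test_bam(dir, "s1", reads)
  counts <- count_fragment_reads(bam, frag)
  # five reads overlap [1000,1026] by >= 1 bp; the read at 2000 does not
  expect_equal(as.numeric(counts), 5)
})

test_that("multi-mapped reads are excluded by default and 1/NH in fractional mode", {
  dir <- withr::local_tempdir()
  frag <- toy_fragments(c(1000L, 3000L), c(1026L, 3026L))
  reads <- data.frame(
    qname = c("u1", "mm", "mm"),
    flag = c(0L, 0L, 256L),
    pos = c(1005L, 1010L, 3010L),
    nh = c(1L, 2L, 2L), stringsAsFactors = FALSE)
  bam <- write_test_bam(dir, "s1", reads)
  expect_equal(as.numeric(count_fragment_reads(bam, frag)), c(1, 0))
  multi <- count_fragment_reads(bam, frag, counting_mode(count_multimapped = TRUE))
  expect_equal(as.numeric(multi), c(2, 1))
  frac <- count_fragment_reads(bam, frag, counting_mode(fractional = TRUE))
  expect_equal(as.numeric(frac), c(1.5, 0.5))
  # fractional conservation: the NH=2 read contributes exactly 1 in total
  expect_equal(sum(frac) - 1, 1)
})

test_that("a read spanning two overlapping fragments counts toward both", {
  dir <- withr::local_tempdir()
  frag <- toy_fragments(c(1000L, 1010L), c(1026L, 1036L))
  reads <- data.frame(qname = "r1", flag = 0L, pos = 1005L, nh = 1L,
                      stringsAsFactors = FALSE)
  bam <- write_test_bam(dir, "s1", reads)
  expect_equal(as.numeric(count_fragment_reads(bam, frag)), c(1, 1))
})

test_that("missing index and chromosome mismatches are hard errors", {
  dir <- withr::local_tempdir()
  frag <- toy_fragments(1000L, 1026L)
  reads <- data.frame(qname = "r1", flag = 0L, pos = 1005L, nh = 1L,
                      stringsAsFactors = FALSE)
  bam <- write_test_bam(dir, "s1", reads)
  unlink(paste0(bam, ".bai"))
  expect_error(count_fragment_reads(bam, frag), "index")
  bam2 <- write_test_bam(dir, "s2", reads)
  frag_bad <- frag
  frag_bad$chrom <- "chr_other"
  expect_error(count_fragment_reads(bam2, frag_bad), "chr_other")
})

test_that("cohort jobs are worker-invariant and track per-sample status", {
  fx <- fixture_cohort()
  regions <- load_reference(fx$regions_fa, fx$regions_bed, assembly = "toy")
  db <- build_database(regions)
  peps <- read_peptides(fx$peptides_fa)
  frags <- merge_fragments(hit_to_fragment(find_peptide_hits(peps, db), db))
  td <- withr::local_tempdir()
  fc1 <- run_quantification_jobs(fx$manifest, frags, counting_mode(),
                                 workers = 1L, task_dir = td, task_id = "t1")
  fc4 <- run_quantification_jobs(fx$manifest[rev(seq_len(nrow(fx$manifest))), ],
                                 frags, counting_mode(), workers = 4L)
  expect_identical(fc1$counts, fc4$counts)
  st <- task_status(td, "t1")
  expect_equal(length(st$samples), nrow(fx$manifest))
  expect_true(all(vapply(st$samples, function(s) s$status, "") == "done"))
  expect_error(task_status(td, "nope"), "Unknown task id")
  # a failing sample is withheld, not fatal
  broken <- fx$manifest
  broken$alignment_path[1] <- file.path(td, "missing.bam")
  fcb <- run_quantification_jobs(broken, frags, counting_mode())
  expect_equal(ncol(fcb$counts), nrow(fx$manifest) - 1L)
  expect_equal(fcb$status[[broken$sample_id[1]]]$status, "failed")
})

test_that("partial results merge unless a sample is duplicated", {
  fx <- fixture_cohort()
  regions <- load_reference(fx$regions_fa, fx$regions_bed, assembly = "toy")
  db <- build_database(regions)
  peps <- read_peptides(fx$peptides_fa)
  frags <- merge_fragments(hit_to_fragment(find_peptide_hits(peps, db), db))
  half1 <- fx$manifest[1:2, ]
  half2 <- fx$manifest[3:4, ]
  fc1 <- run_quantification_jobs(half1, frags, counting_mode())
  fc2 <- run_quantification_jobs(half2, frags, counting_mode())
  full <- run_quantification_jobs(fx$manifest, frags, counting_mode())
  merged <- merge_count_partials(list(fc1, fc2))
  expect_equal(merged$counts[, colnames(full$counts)], full$counts)
  expect_error(merge_count_partials(list(fc1, fc1)), "Duplicate")
})

test_that("cohort aggregation sums groups and most-expressed applies tie rules", {
  frag <- toy_fragments(c(100L, 400L, 700L), c(126L, 426L, 726L),
                        peptide_id = c("p1", "p1", "p2"))
  counts <- matrix(c(2, 0, 0,
                     3, 5, 0,
                     4, 5, 0), ncol = 3,
                   dimnames = list(paste(frag$peptide_id, frag$fragment_id,
                                         sep = "|"),
                                   c("T1", "T2", "N1")))
  manifest <- data.frame(sample_id = c("T1", "T2", "N1"),
                         patient_id = c("a", "b", "a"),
                         group = c("tumor", "tumor", "normal"),
                         alignment_path = "x", stringsAsFactors = FALSE)
  fc <- structure(list(counts = counts, fragments = frag,
                       mode = counting_mode(), manifest = manifest,
                       totals = NULL, task_id = "t", status = NULL),
                  class = "fragment_counts")
  agg <- aggregate_cohort(fc)
  expect_equal(agg$tumor_reads, c(5, 5, 0))
  expect_equal(agg$normal_reads, c(4, 5, 0))
  expect_equal(agg$total_reads, c(9, 10, 0))
  top <- most_expressed_tissue(agg)
  # p1: fragment 2 wins on total (10 > 9)
  expect_equal(top$start[top$peptide_id == "p1"], 400L)
  expect_equal(top$status, c("ok", "no read"))
  # tie on total: smaller start wins
  agg2 <- agg
  agg2$total_reads[2] <- 9
  expect_equal(most_expressed_tissue(agg2)$start[1], 100L)
  # ranking by tumor reads is available
  agg3 <- agg
  agg3$tumor_reads <- c(7, 5, 0)
  expect_equal(most_expressed_tissue(agg3, rank_by = "tumor")$start[1], 100L)
  # sample missing from the manifest is an error
  expect_error(aggregate_cohort(fc, manifest[1:2, ]), "N1")
})

test_that("per-sample argmax emits the literal 'no read' for zero cells", {
  frag <- toy_fragments(c(100L, 400L), c(126L, 426L), peptide_id = "p1")
  counts <- matrix(c(5, 5,
                     0, 0), ncol = 2,
                   dimnames = list(paste(frag$peptide_id, frag$fragment_id,
                                         sep = "|"), c("S1", "S2")))
  fc <- structure(list(counts = counts, fragments = frag,
                       mode = counting_mode(), manifest = NULL,
                       totals = NULL, task_id = "t", status = NULL),
                  class = "fragment_counts")
  tab <- most_expressed_per_sample(fc)
  expect_equal(tab$S2, "no read")
  # equal nonzero counts: smaller coordinate wins
  expect_equal(tab$S1, "chrT:100-126(+)")
})

test_that("fixture counts recover the planted truth exactly", {
  fx <- fixture_cohort()
  regions <- load_reference(fx$regions_fa, fx$regions_bed, assembly = "toy")
  db <- build_database(regions)
  peps <- read_peptides(fx$peptides_fa)
  frags <- merge_fragments(hit_to_fragment(find_peptide_hits(peps, db), db))
  fc <- run_quantification_jobs(fx$manifest, frags, counting_mode())
  expect_equal(unname(fc$counts),
               unname(fx$unique_counts[, colnames(fc$counts)]))
  frac <- run_quantification_jobs(fx$manifest, frags,
                                  counting_mode(fractional = TRUE))
  expect_equal(unname(frac$counts),
               unname(fx$fractional_counts[, colnames(frac$counts)]))
})
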