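fixture_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_cohort()
      regions <- load_reference(fx$regions_fa, fx$regions_bed,
                                assembly = "toy")
      db <- build_database(regions)
      peps <- read_peptides(fx$peptides_fa)
      frags <- merge_fragments(hit_to_fragment(find_peptide_hits(peps, db),
                                               db))
      fc <- run_quantification_jobs(fx$manifest, frags, counting_mode())
      cache <<- list(fx = fx, db = db, frags = frags, fc = fc)
    }
    cache
  }
})

test_that("validation sequences read in coding orientation on both strands", {
  pp <- fixture_pipeline()
  vs <- validation_sequence(pp$frags, pp$fx$genome, flank = 60L)
  # the demarcated coding part always translates to the peptide (asserted
  # internally too) and the annotated string is UP[CODING]DOWN
  expect_equal(vapply(vs$coding,
                      function(d) six_frame_translate(d)[["+1"]],
                      character(1), USE.NAMES = FALSE),
               vs$peptide)
  expect_equal(vs$annotated_sequence,
               paste0(vs$upstream_context, "[", vs$coding, "]",
                      vs$downstream_context))
  expect_true(all(nchar(vs$upstream_context) <= 60L))
  # for a '-' fragment the whole window is reverse-complemented: the coding
  # part must differ from the plus-strand genomic window
  minus <- vs[vs$strand == "-", ][1, ]
  plus_window <- hervtrace:::get_genome_seq(pp$fx$genome, minus$chrom,
                                            minus$start, minus$end)
  expect_equal(minus$coding, oracle_revcomp(plus_window))
  # contiguity: up + coding + down is the contiguous coding-strand window
  whole <- hervtrace:::get_genome_seq(
    pp$fx$genome, minus$chrom, max(1L, minus$start - 60L), minus$end + 60L)
  expect_equal(paste0(minus$upstream_context, minus$coding,
                      minus$downstream_context), oracle_revcomp(whole))
})

test_that("flank is clipped at contig bounds without padding", {
  dir <- withr::local_tempdir()
  genome <- file.path(dir, "g.fa")
  make_genome(genome, n_contigs = 1L, contig_len = 1000L, seed = 3L)
  window <- hervtrace:::get_genome_seq(genome, "ctg1", 4L, 30L)
  pep <- six_frame_translate(window)[["+1"]]   # whatever the window encodes
  f <- data.frame(peptide_id = "p", peptide = pep, chrom = "ctg1",
                  start = 4L, end = 30L, strand = "+",
                  fragment_id = "ctg1:4-30(+)", stringsAsFactors = FALSE)
  vs <- validation_sequence(f, genome, flank = 60L)
  expect_equal(nchar(vs$upstream_context), 3L)     # truncated, not padded
  expect_equal(nchar(vs$downstream_context), 60L)
  f_off <- f
  f_off$start <- 990L
  f_off$end <- 990L + 26L
  expect_error(validation_sequence(f_off, genome), "contig")
})

test_that("the three summary tables are written with consistent content", {
  pp <- fixture_pipeline()
  out_dir <- withr::local_tempdir()
  tabs <- build_summary_tables(pp$fc, genome = pp$fx$genome,
                               out_dir = out_dir)
  expect_true(all(file.exists(tabs$paths)))
  t1 <- tabs$per_fragment_all_samples
  t2 <- tabs$most_expressed_tissue
  t3 <- tabs$most_expressed_per_sample
  # table 1: every fragment x sample count present
  expect_equal(nrow(t1), nrow(pp$frags))
  expect_true(all(colnames(pp$fc$counts) %in% colnames(t1)))
  # table 2: tumor <= total on every row, validation sequence attached
  expect_true(all(t2$tumor_reads <= t2$total_reads))
  expect_true(all(grepl("\\[[ACGT]+\\]", t2$validation_sequence)))
  # table 2 matches a direct most-expressed computation
  direct <- most_expressed_tissue(aggregate_cohort(pp$fc))
  expect_equal(t2$fragment_id, direct$fragment_id)
  # table 3 includes 'no read' for the sample with zeroed nested peptides
  expect_true(any(t3 == "no read"))
  # truth check: the planted most-expressed fragment per peptide
  truth_best <- vapply(split(seq_len(nrow(pp$frags)),
                             pp$frags$peptide_id), function(idx) {
    tot <- rowSums(pp$fx$unique_counts)[idx]
    idx[which.max(tot)]
  }, integer(1))
  expect_equal(t2$fragment_id, pp$frags$fragment_id[truth_best])
})

test_that("zero-count rows can be dropped from the tables", {
  pp <- fixture_pipeline()
  fc <- pp$fc
  # add an all-zero fragment by zeroing one row
  fc$counts[nrow(fc$counts), ] <- 0
  out_dir <- withr::local_tempdir()
  kept <- build_summary_tables(fc, genome = NULL, out_dir = out_dir,
                               drop_zero = TRUE)
  expect_equal(nrow(kept$per_fragment_all_samples),
               sum(rowSums(fc$counts) > 0))
  full <- build_summary_tables(fc, genome = NULL, out_dir = out_dir)
  expect_equal(nrow(full$per_fragment_all_samples), nrow(fc$counts))
})

test_that("an empty fragment set produces headers-only tables", {
  manifest <- data.frame(sample_id = "S1", patient_id = "p", group = "tumor",
                         alignment_path = "x", stringsAsFactors = FALSE)
  fc <- structure(list(
    counts = matrix(numeric(0), nrow = 0, ncol = 1,
                    dimnames = list(NULL, "S1")),
    fragments = merge_fragments(hervtrace:::empty_fragments()),
    mode = counting_mode(), manifest = manifest, totals = NULL,
    task_id = "t", status = NULL), class = "fragment_counts")
  out_dir <- withr::local_tempdir()
  tabs <- build_summary_tables(fc, genome = NULL, out_dir = out_dir)
  expect_true(all(file.exists(tabs$paths)))
  expect_equal(nrow(tabs$per_fragment_all_samples), 0L)
})

test_that("heatmaps render all three layouts with monotone color and drop_zero", {
  pp <- fixture_pipeline()
  out_dir <- withr::local_tempdir()
  p1 <- render_heatmap("peptide_by_group", pp$fc,
                       file.path(out_dir, "h1.png"))
  expect_true(file.exists(p1))
  pep <- pp$frags$peptide_id[1]
  p2 <- render_heatmap("fragment_by_group", pp$fc,
                       file.path(out_dir, "h2.png"), peptide_id = pep)
  p3 <- render_heatmap("fragment_by_sample", pp$fc,
                       file.path(out_dir, "h3.png"), peptide_id = pep)
  expect_true(file.exists(p2) && file.exists(p3))
  expect_error(render_heatmap("fragment_by_group", pp$fc,
                              file.path(out_dir, "h4.png")), "peptide_id")
  # all-zero rows vanish under drop_zero; an all-zero matrix is skipped
  fc0 <- pp$fc
  fc0$counts[] <- 0
  expect_warning(
    res <- render_heatmap("peptide_by_group", fc0,
                          file.path(out_dir, "h5.png"), drop_zero = TRUE),
    "skipping")
  expect_true(is.na(res))
  expect_false(file.exists(file.path(out_dir, "h5.png")))
})
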