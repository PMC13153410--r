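# Deterministic synthetic-data generators: a toy genome with planted
# HERV-like regions, reads and SNVs, plus a machine-readable truth set, so
# the whole pipeline is testable offline.

# Run expr with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a toy genome FASTA
#'
#' Writes a random genome (reproducibly byte-identical per seed) and its
#' samtools-style index.
#'
#' @param path Output FASTA path.
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig in bp (>= 1000).
#' @param gc GC content (default 0.5).
#' @param seed RNG seed fixing all randomness.
#' @return \code{path}, invisibly.
#' @export
make_genome <- function(path, n_contigs = 2L, contig_len = 20000L,
                        gc = 0.5, seed = 1L) {
  stopifnot(contig_len >= 1000L)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_contigs), function(i) random_dna(contig_len, gc),
           character(1))
  })
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- paste0("ctg", seq_len(n_contigs))
  Biostrings::writeXStringSet(set, path, width = 70L)
  Rsamtools::indexFa(path)
  invisible(path)
}

# Deterministic (seeded) reverse translation: one codon sampled per residue.
reverse_translate <- function(peptide) {
  code <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(peptide, "")[[1]], function(aa) {
    cands <- names(code)[code == aa]
    cands[sample.int(length(cands), 1L)]
  }, character(1)), collapse = "")
}

# Mutate one base of a coding window so exactly one residue changes (never
# to a stop). Returns list(dna, pos_in_window, ref, alt).
near_miss <- function(coding) {
  code <- Biostrings::GENETIC_CODE
  L <- nchar(coding) %/% 3L
  ci <- (L %/% 2L) + 1L                       # middle codon
  codon <- substr(coding, 3L * ci - 2L, 3L * ci)
  orig_aa <- code[[codon]]
  for (bp in c(2L, 1L, 3L)) {
    for (b in sample(c("A", "C", "G", "T"))) {
      if (b == substr(codon, bp, bp)) next
      cand <- codon
      substr(cand, bp, bp) <- b
      aa <- code[[cand]]
      if (aa != "*" && aa != orig_aa) {
        dna <- coding
        pos <- 3L * (ci - 1L) + bp
        ref_base <- substr(dna, pos, pos)
        substr(dna, pos, pos) <- b
        return(list(dna = dna, pos = pos, ref = b, alt = ref_base))
      }
    }
  }
  stop("Could not construct a near-miss codon")   # unreachable for 20-aa code
}

#' Plant peptide-coding windows into a genome
#'
#' Edits a genome so that each requested peptide has an in-frame, stop-free
#' coding window on its assigned genomic strand inside a provirus-like
#' region, and writes the region reference (FASTA in region orientation +
#' BED) alongside the edited genome. The standard decoy set can be added:
#' a 1-mismatch near-miss region for the first peptide (with the single
#' enabling SNV recorded) and a duplicated locus (the first region's full
#' window copied elsewhere, forcing a multi-mapping ambiguity).
#'
#' @param genome_path Genome FASTA from [make_genome()] (edited in place:
#'   the planted genome is rewritten to \code{genome_path}).
#' @param plants Data.frame with columns \code{peptide_id, peptide, strand}
#'   (genomic coding strand) and optionally \code{region_strand} (BED strand
#'   of the hosting region; default \code{"+"}).
#' @param out_dir Directory receiving \code{regions.fa}, \code{regions.bed}
#'   and \code{truth.json}.
#' @param seed RNG seed (codon choice and decoy placement).
#' @param region_len Length of each planted region (default 600).
#' @param decoy Add the near-miss decoy region (default TRUE).
#' @param duplicate_locus Add the duplicated-locus region (default TRUE).
#' @return The truth set: a list with \code{fragments} (expected reference
#'   hits: peptide_id, peptide, chrom, start, end, strand, region_id),
#'   \code{enabling_snv} (the SNV converting the decoy into a true coding
#'   window, plus the fragment it enables), and file paths.
#' @export
plant_herv_regions <- function(genome_path, plants, out_dir, seed = 1L,
                               region_len = 600L, decoy = TRUE,
                               duplicate_locus = TRUE) {
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  contigs <- as.character(genome)
  if (is.null(plants$region_strand)) plants$region_strand <- "+"
  max_pep <- max(nchar(plants$peptide))
  if (3L * max_pep + 20L > region_len) stop("Peptide too long for region length")

  n_extra <- as.integer(decoy) + as.integer(duplicate_locus)
  n_regions <- nrow(plants) + n_extra
  gap <- 900L
  # region slots cycle over contigs, spaced so nothing overlaps
  slot <- function(k) {
    ctg <- ((k - 1L) %% length(contigs)) + 1L
    row <- (k - 1L) %/% length(contigs)
    start <- 1000L + row * (region_len + gap)
    if (start + region_len - 1L > nchar(contigs[ctg])) {
      stop("Genome too small for ", n_regions, " regions")
    }
    list(ctg = ctg, start = start, end = start + region_len - 1L)
  }

  res <- with_seed(seed, {
    frag_rows <- list()
    bed_rows <- list()
    region_seqs <- character(0)
    enabling <- NULL
    plant_one <- function(k, peptide_id, peptide, gstrand, rstrand,
                          window_dna = NULL, mismatch = FALSE) {
      s <- slot(k)
      coding <- window_dna %||% reverse_translate(peptide)
      mm <- NULL
      if (mismatch) {
        mm <- near_miss(coding)
        coding <- mm$dna
      }
      insert <- if (gstrand == "+") coding else revcomp_chr(coding)
      off <- ((region_len - nchar(insert)) %/% 2L)
      off <- off - (off %% 3L)                    # stable, frame-agnostic
      fs <- s$start + off
      fe <- fs + nchar(insert) - 1L
      ctg_seq <- contigs[s$ctg]
      substr(ctg_seq, fs, fe) <- insert
      contigs[s$ctg] <<- ctg_seq
      rid <- sprintf("region%02d", k)
      window <- substr(contigs[s$ctg], s$start, s$end)
      region_seqs[rid] <<- if (rstrand == "+") window else revcomp_chr(window)
      chrom_name <- names(contigs)[s$ctg]
      bed_rows[[rid]] <<- data.frame(
        chrom = chrom_name,
        start0 = s$start - 1L, end0 = s$end, name = rid, score = 0L,
        strand = rstrand, stringsAsFactors = FALSE)
      if (mismatch) {
        enabling <<- data.frame(
          chrom = chrom_name, pos = fs + mm$pos - 1L,
          ref = mm$ref, alt = mm$alt, peptide_id = peptide_id,
          peptide = peptide, region_id = rid,
          frag_start = fs, frag_end = fe, frag_strand = gstrand,
          stringsAsFactors = FALSE)
      } else {
        frag_rows[[length(frag_rows) + 1L]] <<- data.frame(
          peptide_id = peptide_id, peptide = peptide,
          chrom = chrom_name, start = fs, end = fe,
          strand = gstrand, region_id = rid, stringsAsFactors = FALSE)
      }
      coding
    }
    k <- 0L
    first_coding <- NULL
    for (i in seq_len(nrow(plants))) {
      k <- k + 1L
      coding <- plant_one(k, plants$peptide_id[i], plants$peptide[i],
                          plants$strand[i], plants$region_strand[i])
      if (i == 1L) first_coding <- coding
    }
    if (duplicate_locus) {
      k <- k + 1L
      plant_one(k, plants$peptide_id[1], plants$peptide[1],
                plants$strand[1], "+", window_dna = first_coding)
    }
    if (decoy) {
      k <- k + 1L
      plant_one(k, plants$peptide_id[1], plants$peptide[1],
                "+", "+", window_dna = first_coding, mismatch = TRUE)
    }
    list(contigs = contigs, frag = do.call(rbind, frag_rows),
         bed = do.call(rbind, bed_rows), region_seqs = region_seqs,
         enabling = enabling)
  })

  # rewrite the edited genome and the region reference
  set <- Biostrings::DNAStringSet(res$contigs)
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, genome_path, width = 70L)
  Rsamtools::indexFa(genome_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa_path <- file.path(out_dir, "regions.fa")
  bed_path <- file.path(out_dir, "regions.bed")
  rset <- Biostrings::DNAStringSet(res$region_seqs)
  Biostrings::writeXStringSet(rset, fa_path, width = 70L)
  utils::write.table(res$bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- list(fragments = res$frag, enabling_snv = res$enabling,
                genome = genome_path, regions_fa = fa_path,
                regions_bed = bed_path)
  jsonlite::write_json(truth[c("fragments", "enabling_snv")],
                       file.path(out_dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  truth
}

#' Simulate per-sample aligned reads over planted fragments
#'
#' Places reads deterministically (stratified start positions) so that read
#' counts over the planted fragments are exact, not statistical, and writes
#' one coordinate-sorted indexed BAM per sample plus a manifest. Optional
#' multi-mapped reads are emitted as primary+secondary alignment pairs with
#' \code{NH:i:2} at two fragment loci. The realized truth counts are
#' recomputed from the placed reads by plain interval arithmetic (reads
#' covering one planted fragment can legitimately overlap a nested
#' neighbour; the truth reflects that).
#'
#' @param genome_path Edited genome FASTA.
#' @param fragments Truth fragment table (chrom, start, end, ...).
#' @param depths Integer matrix, fragments x samples: unique reads to aim
#'   at each fragment.
#' @param groups Named character vector sample_id -> "tumor"/"normal".
#' @param patients Named character vector sample_id -> patient_id.
#' @param out_dir Output directory for BAMs and \code{manifest.tsv}.
#' @param read_len Read length (default 60).
#' @param seed RNG seed (read stagger).
#' @param multimap Optional data.frame \code{(sample_id, frag_i, frag_j, n)}:
#'   n reads each aligned at fragment rows \code{frag_i} (primary) and
#'   \code{frag_j} (secondary), NH = 2.
#' @return List: \code{manifest} (data.frame, also written as TSV),
#'   \code{unique_counts} and \code{fractional_counts} (realized truth
#'   matrices, fragments x samples).
#' @export
simulate_reads <- function(genome_path, fragments, depths, groups, patients,
                           out_dir, read_len = 60L, seed = 1L,
                           multimap = NULL) {
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  contigs <- stats::setNames(as.character(genome), names(genome))
  if (read_len > min(nchar(contigs))) stop("read_len larger than a contig")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- colnames(depths)
  stopifnot(nrow(depths) == nrow(fragments),
            all(samples %in% names(groups)),
            all(samples %in% names(patients)))

  place_read <- function(frag, j) {
    # stagger within the legal overlap window, clipped to the contig
    lo <- max(1L, frag$start - read_len + 1L)
    hi <- min(frag$end, nchar(contigs[frag$chrom]) - read_len + 1L)
    centre <- frag$start - (read_len - (frag$end - frag$start + 1L)) %/% 2L
    pos <- centre + ((j - 1L) %% 7L) - 3L
    min(max(pos, lo), hi)
  }

  manifest <- data.frame(sample_id = samples,
                         patient_id = unname(patients[samples]),
                         group = unname(groups[samples]),
                         alignment_path = file.path(out_dir,
                                                    paste0(samples, ".bam")),
                         stringsAsFactors = FALSE)
  unique_reads <- list()   # per sample: data.frame(chrom, pos, end)
  mm_reads <- list()
  for (s in samples) {
    recs <- list()
    for (f in seq_len(nrow(fragments))) {
      n <- depths[f, s]
      if (n == 0L) next
      frag <- fragments[f, ]
      pos <- vapply(seq_len(n), function(j) place_read(frag, j), integer(1))
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = frag$chrom, pos = pos, stringsAsFactors = FALSE)
    }
    unique_reads[[s]] <- if (length(recs)) do.call(rbind, recs) else
      data.frame(chrom = character(0), pos = integer(0))
    mm <- NULL
    if (!is.null(multimap)) {
      mrows <- multimap[multimap$sample_id == s, , drop = FALSE]
      if (nrow(mrows) > 0L) {
        mm <- do.call(rbind, lapply(seq_len(nrow(mrows)), function(r) {
          fi <- fragments[mrows$frag_i[r], ]
          fj <- fragments[mrows$frag_j[r], ]
          do.call(rbind, lapply(seq_len(mrows$n[r]), function(j) {
            data.frame(chrom = c(fi$chrom, fj$chrom),
                       pos = c(place_read(fi, j), place_read(fj, j)),
                       qname = sprintf("mm_%s_%d_%d", s, r, j),
                       secondary = c(FALSE, TRUE), stringsAsFactors = FALSE)
          }))
        }))
      }
    }
    mm_reads[[s]] <- mm
  }

  # write one SAM -> sorted BAM per sample
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  for (s in samples) {
    ur <- unique_reads[[s]]
    recs <- if (nrow(ur) > 0L) {
      data.frame(qname = sprintf("u_%s_%06d", s, seq_len(nrow(ur))),
                 flag = 0L, chrom = ur$chrom, pos = ur$pos, nh = 1L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(qname = character(0), flag = integer(0), chrom = character(0),
                 pos = integer(0), nh = integer(0))
    }
    mm <- mm_reads[[s]]
    if (!is.null(mm)) {
      recs <- rbind(recs, data.frame(
        qname = mm$qname, flag = ifelse(mm$secondary, 256L, 0L),
        chrom = mm$chrom, pos = mm$pos, nh = 2L, stringsAsFactors = FALSE))
    }
    recs <- recs[order(match(recs$chrom, names(contigs)), recs$pos), ,
                 drop = FALSE]
    lines <- hdr
    if (nrow(recs) > 0L) {
      seqs <- vapply(seq_len(nrow(recs)), function(i) {
        substr(contigs[recs$chrom[i]], recs$pos[i],
               recs$pos[i] + read_len - 1L)
      }, character(1))
      lines <- c(lines, sprintf(
        "%s\t%d\t%s\t%d\t50\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
        recs$qname, recs$flag, recs$chrom, recs$pos, read_len, seqs,
        strrep("I", read_len), recs$nh))
    }
    sam <- file.path(out_dir, paste0(s, ".sam"))
    writeLines(lines, sam)
    Rsamtools::asBam(sam, file.path(out_dir, s), overwrite = TRUE,
                     indexDestination = TRUE)
    unlink(sam)
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # realized truth counts by plain interval arithmetic
  overlap_count <- function(reads, frag, weight = 1) {
    if (is.null(reads) || nrow(reads) == 0L) return(0)
    hit <- reads$chrom == frag$chrom &
      reads$pos <= frag$end & reads$pos + read_len - 1L >= frag$start
    sum(hit) * weight
  }
  uc <- matrix(0, nrow(fragments), length(samples),
               dimnames = list(NULL, samples))
  frc <- uc
  for (s in samples) {
    for (f in seq_len(nrow(fragments))) {
      frag <- fragments[f, ]
      u <- overlap_count(unique_reads[[s]], frag)
      uc[f, s] <- u
      frc[f, s] <- u + overlap_count(mm_reads[[s]], frag, weight = 0.5)
    }
  }
  list(manifest = manifest, unique_counts = uc, fractional_counts = frc)
}

#' Write a minimal single-sample SNV VCF
#'
#' @param path Output VCF path.
#' @param chrom,pos,ref,alt SNV description (1-based, plus-strand REF/ALT).
#' @param sample_id Sample column name.
#' @return \code{path}, invisibly.
#' @export
make_snv_vcf <- function(path, chrom, pos, ref, alt, sample_id) {
  if (any(ref == alt)) stop("alt must differ from ref")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"),
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1/1", chrom, pos, ref, alt))
  writeLines(lines, path)
  invisible(path)
}

#' Build the standard fixture cohort
#'
#' One call producing the canonical offline test bed: a toy genome with the
#' full decoy set (the same peptide planted on both strands, a nested
#' fragment pair from a 15-mer and its internal 9-mer, a region annotated on
#' the BED minus strand, a duplicated locus driving NH=2 multi-mapping, and
#' a near-miss decoy with its enabling SNV), per-sample tumor/normal BAMs
#' with deterministic depths, the sample VCF, and the realized truth set.
#'
#' @param dir Output directory.
#' @param seed RNG seed.
#' @param n_patients Number of patients (each with tumor + normal samples).
#' @param read_len Simulated read length.
#' @return A list with all file paths, the query peptide table, the truth
#'   fragments and realized count matrices, and the multimap design.
#' @export
make_fixture_cohort <- function(dir, seed = 1L, n_patients = 2L,
                                read_len = 60L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- file.path(dir, "genome.fa")
  make_genome(genome, n_contigs = 2L, contig_len = 20000L, seed = seed)
  plants <- data.frame(
    peptide_id = c("pepA_fwd", "pepA_rev", "pepB", "pepC"),
    peptide = c("AVLLPQPPK", "AVLLPQPPK", "NEAIEQVRAICLRAW", "GILLPQPPK"),
    strand = c("+", "-", "+", "-"),
    region_strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  truth <- plant_herv_regions(genome, plants, file.path(dir, "ref"),
                              seed = seed + 1L)
  # queries: one id per distinct peptide, plus the nested internal 9-mer
  peptides <- data.frame(
    peptide_id = c("Q_A", "Q_B", "Q_Bnest", "Q_C", "Q_absent"),
    sequence = c("AVLLPQPPK", "NEAIEQVRAICLRAW", "IEQVRAICL", "GILLPQPPK",
                 "WWWHHHKKK"),
    stringsAsFactors = FALSE)
  # expected fragments per query = planted windows (pepA appears at three
  # loci: fwd, rev, duplicated), plus the nested window inside pepB's
  tf <- truth$fragments
  expect <- rbind(
    transform(tf[tf$peptide == "AVLLPQPPK", ], peptide_id = "Q_A"),
    transform(tf[tf$peptide == "NEAIEQVRAICLRAW", ], peptide_id = "Q_B"),
    {
      b <- tf[tf$peptide == "NEAIEQVRAICLRAW", ]
      off <- as.integer(regexpr("IEQVRAICL", "NEAIEQVRAICLRAW")) - 1L
      b$peptide_id <- "Q_Bnest"
      b$peptide <- "IEQVRAICL"
      b$start <- b$start + 3L * off
      b$end <- b$start + 3L * nchar("IEQVRAICL") - 1L
      b
    },
    transform(tf[tf$peptide == "GILLPQPPK", ], peptide_id = "Q_C"))
  expect <- expect[order(expect$peptide_id, expect$chrom, expect$start), ,
                   drop = FALSE]
  rownames(expect) <- NULL

  samples <- as.vector(t(outer(paste0("p", seq_len(n_patients)),
                               c("tumor", "normal"), paste, sep = "_")))
  groups <- stats::setNames(rep(c("tumor", "normal"), n_patients), samples)
  patients <- stats::setNames(rep(paste0("p", seq_len(n_patients)), each = 2L),
                              samples)
  depths <- outer(seq_len(nrow(expect)), seq_along(samples),
                  function(f, s) (2L * f + 3L * s) %% 6L)
  colnames(depths) <- samples
  # zero out both nested fragments in one sample to exercise "no read"
  depths[expect$peptide_id %in% c("Q_B", "Q_Bnest"), samples[2]] <- 0L
  a_rows <- which(expect$peptide_id == "Q_A")
  multimap <- data.frame(sample_id = samples[1],
                         frag_i = a_rows[1], frag_j = a_rows[length(a_rows)],
                         n = 4L, stringsAsFactors = FALSE)
  sim <- simulate_reads(genome, expect, depths, groups, patients,
                        file.path(dir, "bams"), read_len = read_len,
                        seed = seed + 2L, multimap = multimap)
  vcf <- file.path(dir, "sample.vcf")
  snv <- truth$enabling_snv
  make_snv_vcf(vcf, snv$chrom, snv$pos, snv$ref, snv$alt,
               sample_id = samples[1])
  pep_fa <- file.path(dir, "peptides.fa")
  writeLines(paste0(">", peptides$peptide_id, "\n", peptides$sequence), pep_fa)
  list(dir = dir, genome = genome, regions_fa = truth$regions_fa,
       regions_bed = truth$regions_bed, peptides = peptides,
       peptides_fa = pep_fa, vcf = vcf, manifest = sim$manifest,
       manifest_tsv = file.path(dir, "bams", "manifest.tsv"),
       truth_fragments = expect, enabling_snv = snv,
       unique_counts = sim$unique_counts,
       fractional_counts = sim$fractional_counts,
       multimap = multimap, read_len = read_len)
}
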