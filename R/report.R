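#' Validation-ready DNA sequence context for a fragment
#'
#' Extracts the genomic window \code{fragment +/- flank} (clipped at contig
#' bounds) from the reference plus strand and, for \code{-}-strand fragments,
#' reverse-complements the whole window so the coding subsequence always
#' reads in frame left to right. The coding part is returned both as a
#' separate column and demarcated inside a single annotated string
#' \code{"UP[CODING]DOWN"}. Every coding subsequence is checked to translate
#' exactly to its peptide.
#'
#' @param fragments Merged fragment table.
#' @param genome Indexed genome FASTA path or [Rsamtools::FaFile].
#' @param flank Context length per side in nt (default 60).
#' @return The fragment table with added columns \code{upstream_context,
#'   coding, downstream_context, annotated_sequence, orientation_note}.
#' @export
validation_sequence <- function(fragments, genome, flank = 60L) {
  fa <- if (methods::is(genome, "FaFile")) genome else Rsamtools::FaFile(genome)
  lens <- contig_lengths(fa)
  up <- character(nrow(fragments))
  coding <- character(nrow(fragments))
  down <- character(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    clen <- lens[f$chrom]
    if (is.na(clen)) stop("Contig not in genome: ", f$chrom)
    if (f$end > clen) {
      stop("Fragment beyond contig end: ", f$chrom, ":", f$start, "-", f$end)
    }
    ws <- max(1L, f$start - flank)
    we <- min(clen, f$end + flank)
    window <- get_genome_seq(fa, f$chrom, ws, we)
    a <- f$start - ws + 1L       # coding part within window (plus strand)
    b <- f$end - ws + 1L
    u <- substr(window, 1L, a - 1L)
    cds <- substr(window, a, b)
    d <- substr(window, b + 1L, nchar(window))
    if (f$strand == "-") {
      tmp <- revcomp_chr(window)
      cds <- revcomp_chr(cds)
      u2 <- substr(tmp, 1L, nchar(d))
      d2 <- substr(tmp, nchar(d) + nchar(cds) + 1L, nchar(tmp))
      u <- u2; d <- d2
    }
    pep <- six_frame_translate(cds)[["+1"]]
    if (!identical(pep, f$peptide)) {
      stop("Validation sequence does not translate to peptide for ",
           f$peptide_id, " at ", f$fragment_id, ": got ", pep)
    }
    up[i] <- u; coding[i] <- cds; down[i] <- d
  }
  fragments$upstream_context <- up
  fragments$coding <- coding
  fragments$downstream_context <- down
  fragments$annotated_sequence <- paste0(up, "[", coding, "]", down)
  fragments$orientation_note <- ifelse(
    fragments$strand == "-",
    "coding orientation (reverse complement of reference plus strand)",
    "coding orientation (reference plus strand)")
  fragments
}

#' Write the three summary tables
#'
#' Emits (1) a per-fragment, per-sample count table with validation-ready
#' sequences; (2) the most expressed fragment per peptide at cohort
#' (tissue) level; (3) the most expressed fragment per peptide and sample,
#' with the literal \code{"no read"} for zero-count cells.
#'
#' @param fc A \code{fragment_counts}.
#' @param genome Indexed genome FASTA (for validation sequences); \code{NULL}
#'   omits the sequence columns.
#' @param out_dir Output directory (created if needed).
#' @param drop_zero Drop all-zero fragments from tables 1 and 2's input.
#' @param flank Validation-sequence flank (nt per side).
#' @param rank_by Cohort ranking passed to [most_expressed_tissue()].
#' @return Invisibly, a list with the three data.frames and their paths.
#' @export
build_summary_tables <- function(fc, genome = NULL, out_dir,
                                 drop_zero = FALSE, flank = 60L,
                                 rank_by = "total") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frags <- fc$fragments
  counts <- fc$counts
  if (drop_zero && nrow(frags) > 0L) {
    keep <- rowSums(counts) > 0
    frags <- frags[keep, , drop = FALSE]
    counts <- counts[keep, , drop = FALSE]
  }
  fc_used <- fc
  fc_used$fragments <- frags
  fc_used$counts <- counts

  with_seq <- function(df) {
    if (is.null(genome) || nrow(df) == 0L) return(df)
    vs <- validation_sequence(df, genome, flank = flank)
    df$validation_sequence <- vs$annotated_sequence
    df$coding_sequence <- vs$coding
    df
  }

  t1 <- frags
  if (nrow(frags) > 0L) {
    ord <- order(frags$peptide_id, frags$chrom, frags$start)
    t1 <- cbind(frags[ord, , drop = FALSE],
                as.data.frame(counts[ord, , drop = FALSE],
                              check.names = FALSE))
    rownames(t1) <- NULL
  }
  t1 <- with_seq(t1)

  agg <- aggregate_cohort(fc_used)
  t2 <- if (nrow(agg) > 0L) {
    me <- most_expressed_tissue(agg, rank_by = rank_by)
    me <- with_seq(me)
    cols <- c("peptide_id", "peptide", "fragment_id", "tumor_reads",
              "normal_reads", "total_reads", "strand", "status")
    extra <- intersect(c("validation_sequence", "coding_sequence"),
                       colnames(me))
    me[, c(cols, extra)]
  } else agg
  t3 <- most_expressed_per_sample(fc_used)

  paths <- file.path(out_dir, c("per_fragment_all_samples.tsv",
                                "most_expressed_tissue.tsv",
                                "most_expressed_per_sample.tsv"))
  utils::write.table(t1, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(t2, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(t3, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(per_fragment_all_samples = t1,
                 most_expressed_tissue = t2,
                 most_expressed_per_sample = t3,
                 paths = paths))
}

#' Render one of the three expression heatmaps
#'
#' Kinds: \code{"peptide_by_group"} (peptides x tumor/normal groups),
#' \code{"fragment_by_group"} (one peptide's fragments x groups) and
#' \code{"fragment_by_sample"} (one peptide's fragments x samples). Cells
#' are annotated with their counts and colored on a monotone scale (darker
#' means more reads). \code{drop_zero} removes all-zero rows.
#'
#' @param kind One of the three layout names.
#' @param fc A \code{fragment_counts}.
#' @param out_path Output image path (.png or .pdf).
#' @param peptide_id Required for the two per-peptide kinds.
#' @param drop_zero Drop all-zero rows (default FALSE).
#' @return \code{out_path} invisibly, or \code{NA} when nothing remains to
#'   plot (with a warning).
#' @export
render_heatmap <- function(kind = c("peptide_by_group", "fragment_by_group",
                                    "fragment_by_sample"),
                           fc, out_path, peptide_id = NULL,
                           drop_zero = FALSE) {
  kind <- match.arg(kind)
  grp <- fc$manifest$group[match(colnames(fc$counts),
                                 fc$manifest$sample_id)]
  if (kind == "peptide_by_group") {
    peptides <- sort(unique(fc$fragments$peptide_id))
    mat <- t(vapply(peptides, function(p) {
      idx <- fc$fragments$peptide_id == p
      c(tumor = sum(fc$counts[idx, grp == "tumor", drop = FALSE]),
        normal = sum(fc$counts[idx, grp == "normal", drop = FALSE]))
    }, numeric(2)))
  } else {
    if (is.null(peptide_id)) stop("peptide_id required for kind ", kind)
    idx <- which(fc$fragments$peptide_id == peptide_id)
    labels <- sub("\\(.\\)$", "", fc$fragments$fragment_id[idx])
    if (kind == "fragment_by_group") {
      mat <- cbind(
        tumor = rowSums(fc$counts[idx, grp == "tumor", drop = FALSE]),
        normal = rowSums(fc$counts[idx, grp == "normal", drop = FALSE]))
    } else {
      mat <- fc$counts[idx, , drop = FALSE]
    }
    rownames(mat) <- labels
  }
  if (drop_zero) mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  if (nrow(mat) == 0L) {
    warning("Nothing to plot after zero-row filtering; skipping ", out_path)
    return(invisible(NA_character_))
  }
  pal <- grDevices::colorRampPalette(c("#FFF5F0", "#67000D"))(100)
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                     display_numbers = TRUE, number_format = "%.6g",
                     color = pal, filename = out_path, silent = TRUE)
  invisible(out_path)
}
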