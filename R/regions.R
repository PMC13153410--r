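#' Load a provirus reference (FASTA + BED) into a region table
#'
#' Reads provirus DNA sequences from a FASTA file and their genomic locations
#' from a BED file (0-based half-open on disk; converted to 1-based inclusive
#' here). Records are matched by id: the FASTA record name must equal the BED
#' name column (column 4). The optional BED strand column (column 6) is kept;
#' regions without it get strand \code{NA} and can be oriented later with
#' [annotate_strands()].
#'
#' Region sequences are stored in region orientation: a \code{-} region's
#' sequence is the reverse complement of the reference plus-strand window.
#'
#' @param sequences_path FASTA of region sequences.
#' @param locations_path BED file (chrom, start, end, name[, score, strand]).
#' @param assembly Assembly tag attached to every region (default "hg19").
#' @param permissive If \code{TRUE}, regions failing the length-consistency
#'   check are dropped with a warning instead of raising an error.
#' @return A data.frame of class \code{herv_regions} with columns
#'   \code{region_id, chrom, start, end, strand, sequence, assembly}.
#' @export
load_reference <- function(sequences_path, locations_path,
                           assembly = "hg19", permissive = FALSE) {
  seqs <- Biostrings::readDNAStringSet(sequences_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bed <- utils::read.table(locations_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 4L) {
    stop("BED file must have at least 4 columns (chrom, start, end, name)")
  }
  ids_fa <- names(seqs)
  ids_bed <- bed[[4]]
  miss_fa <- setdiff(ids_fa, ids_bed)
  miss_bed <- setdiff(ids_bed, ids_fa)
  if (length(miss_fa) > 0L || length(miss_bed) > 0L) {
    stop("FASTA/BED id mismatch. In FASTA only: ",
         paste(miss_fa, collapse = ", "),
         "; in BED only: ", paste(miss_bed, collapse = ", "))
  }
  bed <- bed[match(ids_fa, ids_bed), , drop = FALSE]
  strand <- if (ncol(bed) >= 6L) as.character(bed[[6]]) else rep(NA_character_, nrow(bed))
  strand[!strand %in% c("+", "-")] <- NA_character_
  regions <- data.frame(
    region_id = ids_fa,
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    strand = strand,
    sequence = toupper(as.character(seqs)),
    assembly = assembly,
    stringsAsFactors = FALSE
  )
  rownames(regions) <- NULL
  bad_chr <- grepl("[^ACGTN]", regions$sequence)
  if (any(bad_chr)) {
    stop("Non-IUPAC (beyond A,C,G,T,N) characters in regions: ",
         paste(regions$region_id[bad_chr], collapse = ", "))
  }
  bad_len <- (regions$end - regions$start + 1L) != nchar(regions$sequence)
  if (any(bad_len)) {
    msg <- paste0("Region length inconsistent with coordinates: ",
                  paste(regions$region_id[bad_len], collapse = ", "))
    if (permissive) {
      warning(msg, "; dropping these regions")
      regions <- regions[!bad_len, , drop = FALSE]
    } else {
      stop(msg)
    }
  }
  if (any(regions$end < regions$start)) {
    stop("Region with end < start")
  }
  class(regions) <- c("herv_regions", "data.frame")
  regions
}

#' Determine a region's strand by comparison with the reference genome
#'
#' Compares a region sequence position-wise against the reference plus-strand
#' window it claims to occupy, in both orientations. Returns \code{'+'} if the
#' sequence matches the window better than its reverse complement (both as a
#' fraction of matching positions), \code{'-'} for the converse, and \code{NA}
#' when the orientations tie or both fall below \code{min_identity}.
#'
#' @param region_sequence DNA string in region orientation.
#' @param genome An open [Rsamtools::FaFile] or path to an indexed FASTA.
#' @param chrom,start,end 1-based inclusive reference window.
#' @param min_identity Minimum matched fraction to call an orientation
#'   (default 0.90).
#' @return \code{"+"}, \code{"-"}, or \code{NA_character_} (undetermined).
#' @export
annotate_strand <- function(region_sequence, genome, chrom, start, end,
                            min_identity = 0.90) {
  region_sequence <- normalize_dna(region_sequence)
  window <- get_genome_seq(genome, chrom, start, end)
  if (nchar(window) != nchar(region_sequence)) {
    stop("Genome window length differs from region sequence length")
  }
  id_fwd <- position_identity(region_sequence, window)
  id_rev <- position_identity(region_sequence, revcomp_chr(window))
  if (id_fwd == id_rev) return(NA_character_)
  best <- max(id_fwd, id_rev)
  if (best < min_identity) return(NA_character_)
  if (id_fwd > id_rev) "+" else "-"
}

position_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

#' Fill missing region strands from the genome
#'
#' Applies [annotate_strand()] to every region whose strand is \code{NA}.
#' BED-provided strands are never overridden. Regions whose orientation
#' cannot be determined are excluded with a warning.
#'
#' @param regions A \code{herv_regions} table from [load_reference()].
#' @param genome Indexed genome FASTA path or [Rsamtools::FaFile].
#' @param min_identity Passed to [annotate_strand()].
#' @return The region table with strands filled and undetermined regions
#'   removed.
#' @export
annotate_strands <- function(regions, genome, min_identity = 0.90) {
  todo <- which(is.na(regions$strand))
  for (i in todo) {
    regions$strand[i] <- annotate_strand(
      regions$sequence[i], genome,
      regions$chrom[i], regions$start[i], regions$end[i],
      min_identity = min_identity
    )
  }
  undet <- is.na(regions$strand)
  if (any(undet)) {
    warning("Excluding region(s) with undetermined orientation: ",
            paste(regions$region_id[undet], collapse = ", "))
    regions <- regions[!undet, , drop = FALSE]
  }
  regions
}

# Extract a plus-strand subsequence from an indexed genome FASTA.
get_genome_seq <- function(genome, chrom, start, end) {
  fa <- if (methods::is(genome, "FaFile")) genome else Rsamtools::FaFile(genome)
  if (!file.exists(paste0(BiocGenerics::path(fa), ".fai"))) {
    Rsamtools::indexFa(BiocGenerics::path(fa))
  }
  contig_len <- contig_lengths(fa)[chrom]
  if (is.na(contig_len)) stop("Contig not found in genome: ", chrom)
  if (end > contig_len) {
    stop("Window ", chrom, ":", start, "-", end,
         " extends beyond contig end (", contig_len, ")")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  toupper(as.character(Rsamtools::scanFa(fa, gr)[[1]]))
}

contig_lengths <- function(fa) {
  idx <- Rsamtools::scanFaIndex(fa)
  stats::setNames(GenomicRanges::width(idx),
                  as.character(GenomicRanges::seqnames(idx)))
}

#' @export
print.herv_regions <- function(x, ...) {
  cat("HERV region reference:", nrow(x), "region(s) on",
      length(unique(x$chrom)), "contig(s),",
      sum(is.na(x$strand)), "without strand annotation\n")
  invisible(x)
}
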