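#' Map an ORF back to reference genome coordinates
#'
#' Converts an ORF's (frame, amino-acid offset, length) bookkeeping into a
#' 1-based inclusive interval on the reference plus strand, together with the
#' genomic coding strand. The nucleotide interval in region-sequence
#' coordinates is \code{[3*offset + frame_shift, +3*protein_len)} along the
#' frame's reading orientation; this is folded through the region's own strand
#' to reach reference plus-strand coordinates. The genomic strand is the
#' composition of region strand and frame direction (a reverse frame on a
#' \code{+} region codes on \code{-}, and vice versa).
#'
#' @param region One row of a \code{herv_regions} table (list or data.frame).
#' @param frame Frame label, one of \code{"+1","+2","+3","-1","-2","-3"}.
#' @param frame_offset_aa 0-based amino-acid offset within the frame
#'   translation.
#' @param protein_len ORF length in residues.
#' @return A one-row data.frame: \code{chrom, start, end, strand, assembly}.
#' @export
map_orf_to_genome <- function(region, frame, frame_offset_aa, protein_len) {
  frame <- as.character(frame)
  stopifnot(length(frame) == 1L,
            frame %in% c("+1", "+2", "+3", "-1", "-2", "-3"),
            region$strand %in% c("+", "-"),
            length(frame_offset_aa) == length(protein_len))
  len <- region$end - region$start + 1L
  shift <- as.integer(substring(frame, 2L)) - 1L
  fwd_frame <- startsWith(frame, "+")
  nt0 <- shift + 3L * frame_offset_aa
  l3 <- 3L * protein_len
  if (fwd_frame) {
    a <- nt0
    b <- nt0 + l3 - 1L
  } else {
    a <- len - nt0 - l3
    b <- len - nt0 - 1L
  }
  if (any(a < 0L) || any(b >= len)) {
    stop("ORF interval escapes region bounds (frame bookkeeping bug): ",
         region$region_id)
  }
  if (region$strand == "+") {
    gs <- region$start + a
    ge <- region$start + b
  } else {
    gs <- region$end - b
    ge <- region$end - a
  }
  genomic_strand <- if (fwd_frame == (region$strand == "+")) "+" else "-"
  data.frame(chrom = region$chrom, start = as.integer(gs),
             end = as.integer(ge), strand = genomic_strand,
             assembly = region$assembly, stringsAsFactors = FALSE,
             row.names = NULL)
}

# All six-frame ORFs of one region, one row per ORF occurrence with its
# placement; pre-deduplication.
region_orf_occurrences <- function(region, min_orf_len = 1L) {
  tr <- six_frame_translate(region$sequence)
  rows <- lapply(names(tr), function(f) {
    orfs <- extract_orfs(tr[[f]], min_len = min_orf_len)
    if (nrow(orfs) == 0L) return(NULL)
    pl <- map_orf_to_genome(region, f, orfs$offset, nchar(orfs$protein))
    cbind(data.frame(region_id = region$region_id, frame = f,
                     frame_offset = orfs$offset, protein = orfs$protein,
                     stringsAsFactors = FALSE),
          pl)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), frame = character(0),
                      frame_offset = integer(0), protein = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      assembly = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Collapse duplicate ORFs within one region
#'
#' Entries with identical protein strings (within one region and provenance)
#' collapse to a single ORF; the union of their genomic placements is
#' retained. Output order is deterministic: ORFs are sorted by their first
#' placement's coordinates.
#'
#' @param occurrences Data.frame of ORF occurrences as produced internally by
#'   the database builder: one row per occurrence with columns
#'   \code{region_id, frame, frame_offset, protein, chrom, start, end,
#'   strand, assembly}.
#' @return A list with \code{orfs} (one row per distinct protein) and
#'   \code{placements} (one row per retained placement, keyed by row index
#'   into \code{orfs} via \code{orf_key}).
#' @export
dedup_orfs <- function(occurrences) {
  if (nrow(occurrences) == 0L) {
    return(list(orfs = occurrences[0, c("region_id", "frame", "frame_offset",
                                        "protein")],
                placements = cbind(orf_key = integer(0),
                                   occurrences[0, c("frame", "frame_offset",
                                                    "chrom", "start", "end",
                                                    "strand", "assembly")])))
  }
  stopifnot(length(unique(occurrences$region_id)) == 1L)
  occurrences <- occurrences[order(occurrences$chrom, occurrences$start,
                                   occurrences$end, occurrences$strand,
                                   occurrences$frame), , drop = FALSE]
  key <- match(occurrences$protein, unique(occurrences$protein))
  first <- !duplicated(key)
  orfs <- occurrences[first, c("region_id", "frame", "frame_offset", "protein"),
                      drop = FALSE]
  rownames(orfs) <- NULL
  placements <- cbind(orf_key = key,
                      occurrences[, c("frame", "frame_offset", "chrom",
                                      "start", "end", "strand", "assembly"),
                                  drop = FALSE])
  rownames(placements) <- NULL
  list(orfs = orfs, placements = placements)
}

#' Build the six-frame ORF database from a region reference
#'
#' Predicts the ORFs of every region in all six frames, collapses per-region
#' duplicates (the union of placements is kept), localizes every ORF on the
#' reference genome, and verifies the round-trip invariant: translating each
#' placement's coding-orientation genomic subsequence reproduces the ORF
#' protein exactly.
#'
#' @param regions A \code{herv_regions} table; every region must have a
#'   strand (see [annotate_strands()]).
#' @param min_orf_len Minimum ORF length in residues (default 1).
#' @param verify Check the placement round-trip invariant (default TRUE).
#' @return An object of class \code{orf_db}: a list with elements
#'   \code{format_version}, \code{assembly}, \code{regions}, \code{orfs}
#'   (orf_id, region_id, frame, frame_offset, protein, provenance) and
#'   \code{placements} (orf_id, frame, frame_offset, chrom, start, end,
#'   strand, assembly).
#' @export
build_database <- function(regions, min_orf_len = 1L, verify = TRUE) {
  if (nrow(regions) == 0L) stop("Empty region set")
  if (any(is.na(regions$strand))) {
    stop("Regions without strand annotation: ",
         paste(regions$region_id[is.na(regions$strand)], collapse = ", "),
         " (run annotate_strands() first)")
  }
  per_region <- lapply(seq_len(nrow(regions)), function(i) {
    region <- regions[i, , drop = FALSE]
    dd <- dedup_orfs(region_orf_occurrences(region, min_orf_len))
    if (nrow(dd$orfs) == 0L) return(NULL)
    ids <- sprintf("%s:orf%04d", region$region_id, seq_len(nrow(dd$orfs)))
    orfs <- cbind(orf_id = ids, dd$orfs, provenance = "reference",
                  stringsAsFactors = FALSE)
    placements <- cbind(orf_id = ids[dd$placements$orf_key],
                        dd$placements[, -1, drop = FALSE],
                        stringsAsFactors = FALSE)
    list(orfs = orfs, placements = placements)
  })
  per_region <- per_region[!vapply(per_region, is.null, logical(1))]
  db <- structure(list(
    format_version = 1L,
    assembly = regions$assembly[1],
    regions = regions,
    orfs = do.call(rbind, lapply(per_region, `[[`, "orfs")),
    placements = do.call(rbind, lapply(per_region, `[[`, "placements"))
  ), class = "orf_db")
  rownames(db$orfs) <- NULL
  rownames(db$placements) <- NULL
  if (verify) verify_roundtrip(db)
  db
}

# Recover the plus-strand genomic DNA of an interval from the stored region
# sequences (no genome FASTA needed).
region_window_dna <- function(region, start, end) {
  if (start < region$start || end > region$end) {
    stop("Interval outside region bounds")
  }
  if (region$strand == "+") {
    substr(region$sequence, start - region$start + 1L,
           end - region$start + 1L)
  } else {
    revcomp_chr(substr(region$sequence, region$end - end + 1L,
                       region$end - start + 1L))
  }
}

# Assert that every placement translates back to its ORF protein.
verify_roundtrip <- function(db) {
  if (is.null(db$placements) || nrow(db$placements) == 0L) return(invisible(TRUE))
  prot <- db$orfs$protein[match(db$placements$orf_id, db$orfs$orf_id)]
  reg_idx <- match(db$orfs$region_id[match(db$placements$orf_id,
                                           db$orfs$orf_id)],
                   db$regions$region_id)
  # round-trip only meaningful for reference provenance (variant ORFs encode
  # sample alleles absent from the reference sequence)
  prov <- db$orfs$provenance[match(db$placements$orf_id, db$orfs$orf_id)]
  idx <- which(prov == "reference")
  if (length(idx) == 0L) return(invisible(TRUE))
  dna <- vapply(idx, function(i) {
    region <- db$regions[reg_idx[i], , drop = FALSE]
    d <- region_window_dna(region, db$placements$start[i],
                           db$placements$end[i])
    if (db$placements$strand[i] == "-") revcomp_chr(d) else d
  }, character(1))
  got <- translate_dna_vec(dna)
  bad <- which(got != prot[idx])
  if (length(bad) > 0L) {
    i <- idx[bad[1]]
    stop("Placement round-trip failed for ", db$placements$orf_id[i],
         ": expected ", prot[i], ", got ", got[bad[1]])
  }
  invisible(TRUE)
}

#' Serialize an ORF database to disk
#'
#' The on-disk form is a single-file key-value store (a serialized named list)
#' carrying a format-version header; [load_orf_db()] refuses files with an
#' unknown version.
#'
#' @param db An \code{orf_db}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_orf_db <- function(db, path) {
  stopifnot(inherits(db, "orf_db"))
  saveRDS(unclass(db), path)
  invisible(path)
}

#' @rdname save_orf_db
#' @export
load_orf_db <- function(path) {
  if (!file.exists(path)) stop("ORF database file not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format_version, 1L)) {
    stop("Not an ORF database file (missing or unknown format version): ", path)
  }
  structure(obj, class = "orf_db")
}

#' Export the ORF coordinate database as TSV
#'
#' @param db An \code{orf_db}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
export_orf_coordinates <- function(db, path) {
  pl <- db$placements
  idx <- match(pl$orf_id, db$orfs$orf_id)
  out <- data.frame(region_id = db$orfs$region_id[idx],
                    orf_id = pl$orf_id,
                    chrom = pl$chrom, start = pl$start, end = pl$end,
                    strand = pl$strand, frame = pl$frame,
                    protein_length = nchar(db$orfs$protein[idx]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.orf_db <- function(x, ...) {
  prov <- table(x$orfs$provenance)
  cat("ORF database (", x$assembly, "): ", nrow(x$regions), " region(s), ",
      nrow(x$orfs), " ORF(s), ", nrow(x$placements), " placement(s)\n",
      sep = "")
  if (length(prov) > 1L) {
    cat("  provenance:", paste(names(prov), prov, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
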