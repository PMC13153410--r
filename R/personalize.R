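#' Read single-nucleotide variants from a VCF
#'
#' Parses a (plain or bgzipped) VCF and keeps biallelic-expanded SNV records:
#' multi-allelic rows are split into one record per single-base alternate;
#' indels, MNVs and symbolic alleles are skipped with a counted warning. By
#' default only records with FILTER \code{PASS} or \code{.} are kept.
#'
#' @param vcf_path VCF file path.
#' @param sample_id Sample label to attach to every record (defaults to the
#'   first sample column name, or the file base name for site-only VCFs).
#' @param all_filters Keep records regardless of FILTER status.
#' @return A data.frame of class \code{snv_set} with columns
#'   \code{chrom, pos, ref, alt, filter, sample_id}; attributes
#'   \code{n_records} (rows parsed) and \code{n_skipped_non_snv}.
#' @export
read_snvs <- function(vcf_path, sample_id = NULL, all_filters = FALSE) {
  if (!file.exists(vcf_path)) stop("VCF not readable: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)    # single-record VCF drops to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    samples <- colnames(v@gt)[-1]
    sample_id <- if (length(samples) >= 1L) samples[1] else
      sub("\\.vcf(\\.gz)?$", "", basename(vcf_path))
  }
  n_records <- nrow(fix)
  if (n_records == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      filter = character(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_records") <- 0L
    attr(out, "n_skipped_non_snv") <- 0L
    class(out) <- c("snv_set", "data.frame")
    return(out)
  }
  filt <- fix$FILTER
  filt[is.na(filt)] <- "."
  keep_filter <- all_filters | filt %in% c("PASS", ".")
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(n_records)) {
    if (!keep_filter[i]) next
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- toupper(fix$REF[i])
    for (alt in toupper(alts)) {
      is_snv <- nchar(ref) == 1L && nchar(alt) == 1L &&
        ref %in% c("A", "C", "G", "T") && alt %in% c("A", "C", "G", "T") &&
        ref != alt
      if (!is_snv) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alt, filter = filt[i], sample_id = sample_id,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), filter = character(0),
               sample_id = character(0), stringsAsFactors = FALSE)
  attr(out, "n_records") <- n_records
  attr(out, "n_skipped_non_snv") <- n_skipped
  class(out) <- c("snv_set", "data.frame")
  out
}

#' Assign SNVs to the regions they overlap
#'
#' Keeps only SNVs whose position falls inside a region's interval and checks
#' each kept record's REF allele against the region's own base at that
#' position (a mismatch indicates a region/assembly mix-up and is an error).
#'
#' @param snvs An \code{snv_set} (or compatible data.frame).
#' @param regions A \code{herv_regions} table.
#' @return A named list (by \code{region_id}) of per-region SNV data.frames;
#'   attribute \code{n_outside} counts records overlapping no region.
#' @export
select_overlapping_snvs <- function(snvs, regions) {
  out <- stats::setNames(vector("list", nrow(regions)), regions$region_id)
  n_outside <- 0L
  for (i in seq_len(nrow(snvs))) {
    hit <- which(regions$chrom == snvs$chrom[i] &
                   regions$start <= snvs$pos[i] &
                   snvs$pos[i] <= regions$end)
    if (length(hit) == 0L) {
      n_outside <- n_outside + 1L
      next
    }
    for (j in hit) {
      region <- regions[j, , drop = FALSE]
      base <- region_base_at(region, snvs$pos[i])
      if (base != snvs$ref[i]) {
        stop("VCF REF mismatch at ", snvs$chrom[i], ":", snvs$pos[i],
             " — region ", region$region_id, " has ", base,
             ", VCF says ", snvs$ref[i],
             " (region/assembly mismatch?)")
      }
      out[[region$region_id]] <- rbind(out[[region$region_id]],
                                       snvs[i, , drop = FALSE])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "n_outside") <- n_outside
  out
}

# Reference plus-strand base at genomic position pos, read from the stored
# region sequence (which is in region orientation).
region_base_at <- function(region, pos) {
  if (region$strand == "+") {
    substr(region$sequence, pos - region$start + 1L, pos - region$start + 1L)
  } else {
    comp_base(substr(region$sequence, region$end - pos + 1L,
                     region$end - pos + 1L))
  }
}

#' Apply SNVs to a region sequence
#'
#' Substitutes each SNV's alternate allele into the region sequence. The
#' region sequence is stored in region orientation, so on a \code{-} region
#' the complement of the alternate is written at the mirrored offset
#' \code{end - pos}. All SNVs of a region are applied jointly to one variant
#' haplotype; sites with several alternates expand combinatorially, one
#' variant sequence per alternate combination. With \code{joint = FALSE}
#' each SNV instead yields its own singly-edited sequence.
#'
#' @param region One row of a \code{herv_regions} table.
#' @param snvs Data.frame of SNVs overlapping the region.
#' @param joint Apply all SNVs together (default) or one at a time.
#' @return A list of variant descriptors, each with \code{sequence} (the
#'   edited region-orientation DNA) and \code{variants} (the SNV rows
#'   applied). Zero-SNV input returns an empty list.
#' @export
apply_snvs <- function(region, snvs, joint = TRUE) {
  if (is.null(snvs) || nrow(snvs) == 0L) return(list())
  if (region$strand == "+") {
    offs <- snvs$pos - region$start + 1L
    alts <- snvs$alt
  } else {
    offs <- region$end - snvs$pos + 1L
    alts <- comp_base(snvs$alt)
  }
  if (!joint) {
    return(lapply(seq_len(nrow(snvs)), function(i) {
      s <- region$sequence
      substr(s, offs[i], offs[i]) <- alts[i]
      list(sequence = s, variants = snvs[i, , drop = FALSE])
    }))
  }
  # group alternates by position, expand one haplotype per combination
  by_pos <- split(seq_len(nrow(snvs)), offs)
  combos <- expand.grid(lapply(by_pos, identity), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(k) {
    idx <- as.integer(unlist(combos[k, ], use.names = FALSE))
    s <- region$sequence
    for (i in idx) substr(s, offs[i], offs[i]) <- alts[i]
    list(sequence = s, variants = snvs[idx, , drop = FALSE])
  })
}

#' Build a per-sample personalized ORF database
#'
#' Layers a sample's accumulated SNVs onto the reference database: regions
#' with no overlapping SNV reuse their reference entries unchanged; affected
#' regions additionally contribute the six-frame ORFs of each variant
#' haplotype, tagged with the sample id and the variants applied. Variant
#' ORFs whose protein already exists among the region's reference ORFs are
#' collapsed onto the reference entry. Personalization is additive: no
#' reference ORF is ever removed.
#'
#' @param reference_db An \code{orf_db} built by [build_database()].
#' @param vcf_path Sample VCF path.
#' @param sample_id Sample label (default from the VCF).
#' @param min_orf_len Minimum variant-ORF length (default 1).
#' @param joint Multi-SNV policy of [apply_snvs()].
#' @param all_filters Passed to [read_snvs()].
#' @return An \code{orf_db} containing the reference entries plus the
#'   sample's variant ORFs (provenance \code{"<sample>:chrom:pos:ref>alt[;...]"}).
#' @export
build_personalized_db <- function(reference_db, vcf_path, sample_id = NULL,
                                  min_orf_len = 1L, joint = TRUE,
                                  all_filters = FALSE) {
  snvs <- read_snvs(vcf_path, sample_id = sample_id,
                    all_filters = all_filters)
  sample_id <- if (nrow(snvs) > 0L) snvs$sample_id[1] else
    (sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(vcf_path)))
  if (any(grepl(paste0("^", sample_id, ":"), reference_db$orfs$provenance))) {
    stop("Database already holds personalized entries for sample ", sample_id)
  }
  per_region <- select_overlapping_snvs(snvs, reference_db$regions)
  db <- reference_db
  for (rid in names(per_region)) {
    region <- db$regions[db$regions$region_id == rid, , drop = FALSE]
    ref_prot <- db$orfs$protein[db$orfs$region_id == rid &
                                  db$orfs$provenance == "reference"]
    haplotypes <- apply_snvs(region, per_region[[rid]], joint = joint)
    for (h in seq_along(haplotypes)) {
      hap <- haplotypes[[h]]
      vregion <- region
      vregion$sequence <- hap$sequence
      prov <- paste0(sample_id, ":",
                     paste(hap$variants$chrom, hap$variants$pos,
                           paste0(hap$variants$ref, ">", hap$variants$alt),
                           sep = ":", collapse = ";"))
      dd <- dedup_orfs(region_orf_occurrences(vregion, min_orf_len))
      novel <- !(dd$orfs$protein %in% ref_prot)
      if (!any(novel)) next
      keep_keys <- which(novel)
      ids <- sprintf("%s:%s:h%d:orf%04d", rid, sample_id, h,
                     seq_along(keep_keys))
      orfs <- cbind(orf_id = ids,
                    dd$orfs[keep_keys, , drop = FALSE],
                    provenance = prov, stringsAsFactors = FALSE)
      pl_keep <- dd$placements$orf_key %in% keep_keys
      placements <- cbind(
        orf_id = ids[match(dd$placements$orf_key[pl_keep], keep_keys)],
        dd$placements[pl_keep, -1, drop = FALSE],
        stringsAsFactors = FALSE)
      db$orfs <- rbind(db$orfs, orfs)
      db$placements <- rbind(db$placements, placements)
    }
  }
  rownames(db$orfs) <- NULL
  rownames(db$placements) <- NULL
  attr(db, "snv_accounting") <- list(
    n_records = attr(snvs, "n_records"),
    n_skipped_non_snv = attr(snvs, "n_skipped_non_snv"),
    n_outside = attr(per_region, "n_outside"),
    n_applied = sum(vapply(per_region, nrow, integer(1))))
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a
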