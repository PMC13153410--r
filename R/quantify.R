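#' Read-counting mode
#'
#' Controls how alignments are assigned to candidate fragments. Counting is
#' strand-agnostic and an alignment is credited to every fragment it overlaps
#' by at least \code{min_overlap} reference bases (fragments frequently
#' overlap or nest, so no largest-overlap disambiguation is applied). By
#' default only uniquely mapped reads count (primary alignments with
#' \code{NH} absent or 1), each with weight 1. With
#' \code{count_multimapped = TRUE} secondary alignments are included; with
#' \code{fractional = TRUE} each alignment of a read reporting \code{NH = k}
#' counts \code{1/k}.
#'
#' @param count_multimapped Include multi-mapped reads (default FALSE).
#' @param fractional Weight alignments \code{1/NH} (implies
#'   \code{count_multimapped}).
#' @param min_overlap Minimum reference overlap in bp (default 1).
#' @param mapq Minimum mapping quality (default 0).
#' @return A list of class \code{counting_mode}.
#' @export
counting_mode <- function(count_multimapped = FALSE, fractional = FALSE,
                          min_overlap = 1L, mapq = 0L) {
  if (fractional) count_multimapped <- TRUE
  structure(list(count_multimapped = count_multimapped,
                 fractional = fractional,
                 count_overlapping_features = TRUE,
                 min_overlap = as.integer(min_overlap),
                 mapq = as.integer(mapq)),
            class = "counting_mode")
}

#' Count reads over candidate fragments for one sample
#'
#' @param alignment_file Coordinate-sorted, indexed BAM path.
#' @param fragments Merged fragment table (from [merge_fragments()] or
#'   [read_gtf()]).
#' @param mode A [counting_mode()].
#' @return Named numeric vector of per-fragment counts (names are
#'   \code{peptide_id|fragment_id} row keys, in fragment-table order), with
#'   attribute \code{n_assigned} (total assigned alignment weight).
#' @export
count_fragment_reads <- function(alignment_file, fragments,
                                 mode = counting_mode()) {
  if (!file.exists(alignment_file)) {
    stop("Alignment file not found: ", alignment_file)
  }
  bai <- paste0(alignment_file, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", alignment_file))) {
    stop("Missing BAM index (.bai) for ", alignment_file)
  }
  keys <- fragment_keys(fragments)
  counts <- stats::setNames(numeric(nrow(fragments)), keys)
  if (nrow(fragments) == 0L) {
    attr(counts, "n_assigned") <- 0
    return(counts)
  }
  bf <- Rsamtools::BamFile(alignment_file)
  hdr_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  missing_chroms <- setdiff(unique(fragments$chrom), hdr_chroms)
  if (length(missing_chroms) > 0L) {
    stop("Fragment chromosome(s) absent from BAM header of ",
         basename(alignment_file), ": ",
         paste(missing_chroms, collapse = ", "))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "mapq"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(bf, param = param)
  if (length(aln) == 0L) {
    attr(counts, "n_assigned") <- 0
    return(counts)
  }
  meta <- S4Vectors::mcols(aln)
  nh <- meta$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(aln))
  secondary <- bitwAnd(meta$flag, 256L) != 0L
  keep <- meta$mapq >= mode$mapq
  if (!mode$count_multimapped) {
    keep <- keep & !secondary & (is.na(nh) | nh == 1L)
  }
  aln <- aln[keep]
  nh <- nh[keep]
  if (length(aln) == 0L) {
    attr(counts, "n_assigned") <- 0
    return(counts)
  }
  weight <- if (mode$fractional) {
    ifelse(is.na(nh) | nh < 1L, 1, 1 / nh)
  } else rep(1, length(aln))
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom, IRanges::IRanges(fragments$start, fragments$end))
  ov <- GenomicRanges::findOverlaps(GenomicRanges::granges(aln), frag_gr,
                                    minoverlap = mode$min_overlap)
  if (length(ov) > 0L) {
    add <- tapply(weight[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), sum)
    counts[as.integer(names(add))] <- as.numeric(add)
  }
  attr(counts, "n_assigned") <- sum(weight[unique(S4Vectors::queryHits(ov))])
  counts
}

fragment_keys <- function(fragments) {
  paste(fragments$peptide_id, fragments$fragment_id, sep = "|")
}

#' Read a sample manifest
#'
#' TSV with header columns \code{sample_id, patient_id, group,
#' alignment_path}; \code{group} must be \code{tumor} or \code{normal} and
#' sample ids must be unique.
#'
#' @param path Manifest TSV path.
#' @return Validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  need <- c("sample_id", "patient_id", "group", "alignment_path")
  if (!all(need %in% colnames(m))) {
    stop("Manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) stop("Duplicate sample_id in manifest")
  if (!all(m$group %in% c("tumor", "normal"))) {
    stop("Manifest group must be 'tumor' or 'normal'")
  }
  invisible(TRUE)
}

#' Run per-sample counting jobs for a cohort
#'
#' One counting job per manifest sample, executed with up to \code{workers}
#' processes. The merged matrix is identical for any worker count and sample
#' order. A task id tracks per-sample status; when \code{task_dir} is given,
#' the status is written there as \code{<task_id>.json} and can be looked up
#' with [task_status()]. Failed samples are withheld from the matrix and
#' recorded in the status.
#'
#' @param manifest Manifest data.frame (see [read_manifest()]).
#' @param fragments Merged fragment table or a GTF path.
#' @param mode A [counting_mode()].
#' @param workers Max concurrent jobs (default 1).
#' @param task_dir Optional directory for task-status JSON.
#' @param task_id Optional explicit task id (default: derived from time/PID).
#' @return A \code{fragment_counts} object: fragments x samples count
#'   matrix plus fragment table, mode, manifest, per-sample assigned totals,
#'   \code{task_id} and per-sample \code{status}.
#' @export
run_quantification_jobs <- function(manifest, fragments,
                                    mode = counting_mode(), workers = 1L,
                                    task_dir = NULL, task_id = NULL) {
  validate_manifest(manifest)
  if (is.character(fragments) && length(fragments) == 1L) {
    fragments <- read_gtf(fragments)
  }
  manifest <- manifest[order(manifest$sample_id), , drop = FALSE]
  task_id <- task_id %||% sprintf("task-%s-%d",
                                  format(Sys.time(), "%Y%m%d%H%M%S"),
                                  Sys.getpid())
  worker <- function(i) {
    tryCatch(
      list(ok = TRUE,
           counts = count_fragment_reads(manifest$alignment_path[i],
                                         fragments, mode)),
      error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(manifest)), worker,
                       mc.cores = workers, mc.preschedule = FALSE)
  } else {
    lapply(seq_len(nrow(manifest)), worker)
  }
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  counts <- matrix(0, nrow = nrow(fragments), ncol = sum(ok),
                   dimnames = list(fragment_keys(fragments),
                                   manifest$sample_id[ok]))
  totals <- stats::setNames(numeric(sum(ok)), manifest$sample_id[ok])
  j <- 0L
  for (i in which(ok)) {
    j <- j + 1L
    counts[, j] <- as.numeric(results[[i]]$counts)
    totals[j] <- attr(results[[i]]$counts, "n_assigned")
  }
  status <- lapply(seq_len(nrow(manifest)), function(i) {
    list(sample_id = manifest$sample_id[i],
         status = if (ok[i]) "done" else "failed",
         error = if (ok[i]) NULL else results[[i]]$error)
  })
  names(status) <- manifest$sample_id
  fc <- structure(list(counts = counts, fragments = fragments, mode = mode,
                       manifest = manifest, totals = totals,
                       task_id = task_id, status = status),
                  class = "fragment_counts")
  if (!is.null(task_dir)) {
    dir.create(task_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(task_id = task_id,
           samples = lapply(status, function(s) {
             list(sample_id = s$sample_id, status = s$status,
                  error = s$error %||% NA)
           })),
      file.path(task_dir, paste0(task_id, ".json")), auto_unbox = TRUE)
  }
  fc
}

#' Look up the status of a quantification task
#'
#' @param task_dir Directory used by [run_quantification_jobs()].
#' @param task_id Task id to resolve.
#' @return The parsed status list.
#' @export
task_status <- function(task_dir, task_id) {
  path <- file.path(task_dir, paste0(task_id, ".json"))
  if (!file.exists(path)) stop("Unknown task id: ", task_id)
  jsonlite::read_json(path)
}

#' Merge partial count matrices
#'
#' Combines results from separate quantification invocations over the same
#' fragment set (e.g. per-batch runs). Duplicate sample ids across partials
#' are an error; fragment indices must agree.
#'
#' @param partials A list of \code{fragment_counts} objects.
#' @return A single merged \code{fragment_counts}.
#' @export
merge_count_partials <- function(partials) {
  stopifnot(length(partials) >= 1L)
  keys <- lapply(partials, function(p) rownames(p$counts))
  if (!all(vapply(keys, identical, logical(1), y = keys[[1]]))) {
    stop("Partial results cover different fragment sets; cannot merge")
  }
  samples <- unlist(lapply(partials, function(p) colnames(p$counts)))
  if (anyDuplicated(samples)) {
    stop("Duplicate sample id(s) across partial results: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  merged <- partials[[1]]
  merged$counts <- do.call(cbind, lapply(partials, `[[`, "counts"))
  merged$manifest <- do.call(rbind, lapply(partials, `[[`, "manifest"))
  merged$totals <- do.call(c, lapply(partials, `[[`, "totals"))
  merged$status <- do.call(c, lapply(partials, `[[`, "status"))
  merged
}

#' Aggregate counts to tumor/normal cohort level
#'
#' @param fc A \code{fragment_counts}.
#' @param manifest Manifest giving each sample's group (defaults to the one
#'   stored in \code{fc}).
#' @return The fragment table with added \code{tumor_reads, normal_reads,
#'   total_reads} columns.
#' @export
aggregate_cohort <- function(fc, manifest = fc$manifest) {
  samples <- colnames(fc$counts)
  miss <- setdiff(samples, manifest$sample_id)
  if (length(miss) > 0L) {
    stop("Sample(s) missing from manifest: ", paste(miss, collapse = ", "))
  }
  grp <- manifest$group[match(samples, manifest$sample_id)]
  tumor <- rowSums(fc$counts[, grp == "tumor", drop = FALSE])
  normal <- rowSums(fc$counts[, grp == "normal", drop = FALSE])
  out <- fc$fragments
  out$tumor_reads <- as.numeric(tumor)
  out$normal_reads <- as.numeric(normal)
  out$total_reads <- out$tumor_reads + out$normal_reads
  out
}

# shared tie rule: smallest (chrom, start, end, strand) wins
top_fragment_idx <- function(frag_rows, values) {
  best <- max(values)
  cand <- which(values == best)
  cand[order(frag_rows$chrom[cand], frag_rows$start[cand],
             frag_rows$end[cand], frag_rows$strand[cand])][1]
}

#' Most expressed fragment per peptide at cohort level
#'
#' For each peptide, the fragment maximizing \code{total_reads} (or
#' \code{tumor_reads} with \code{rank_by = "tumor"}); ties broken by
#' smallest (chrom, start, end, strand). Peptides whose fragments all have
#' zero reads are flagged \code{"no read"}.
#'
#' @param aggregated Output of [aggregate_cohort()].
#' @param rank_by \code{"total"} (default) or \code{"tumor"}.
#' @return One row per peptide: fragment columns plus \code{tumor_reads,
#'   normal_reads, total_reads} and \code{status} (\code{"ok"}/\code{"no read"}).
#' @export
most_expressed_tissue <- function(aggregated, rank_by = c("total", "tumor")) {
  rank_by <- match.arg(rank_by)
  rows <- lapply(split(seq_len(nrow(aggregated)), aggregated$peptide_id),
                 function(idx) {
    a <- aggregated[idx, , drop = FALSE]
    vals <- if (rank_by == "tumor") a$tumor_reads else a$total_reads
    best <- top_fragment_idx(a, vals)
    out <- a[best, , drop = FALSE]
    out$status <- if (max(a$total_reads) == 0) "no read" else "ok"
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most expressed fragment per peptide and sample
#'
#' For every (peptide, sample) pair, the fragment with the highest count in
#' that sample (ties broken by smallest coordinates); the literal string
#' \code{"no read"} where the peptide has zero counts in that sample.
#'
#' @param fc A \code{fragment_counts}.
#' @return A data.frame with \code{peptide_id} rows and one column per
#'   sample holding a fragment label or \code{"no read"}.
#' @export
most_expressed_per_sample <- function(fc) {
  peptides <- sort(unique(fc$fragments$peptide_id))
  samples <- colnames(fc$counts)
  out <- matrix("no read", nrow = length(peptides), ncol = length(samples),
                dimnames = list(peptides, samples))
  for (p in peptides) {
    idx <- which(fc$fragments$peptide_id == p)
    for (s in samples) {
      vals <- fc$counts[idx, s]
      if (max(vals) > 0) {
        best <- top_fragment_idx(fc$fragments[idx, , drop = FALSE], vals)
        out[p, s] <- fc$fragments$fragment_id[idx[best]]
      }
    }
  }
  data.frame(peptide_id = peptides, out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat("Fragment count matrix: ", nrow(x$counts), " fragment(s) x ",
      ncol(x$counts), " sample(s)\n", sep = "")
  cat("  mode: multimapped=", x$mode$count_multimapped,
      ", fractional=", x$mode$fractional, "\n", sep = "")
  cat("  task:", x$task_id, "\n")
  invisible(x)
}
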