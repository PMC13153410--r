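#' Read query peptides from FASTA or FASTQ
#'
#' Accepts a FASTA (or FASTQ, qualities ignored) of short amino-acid
#' sequences. Sequences are validated against the 20 standard residues and
#' must be at least 3 residues long.
#'
#' @param path Peptide FASTA/FASTQ path.
#' @return A data.frame with columns \code{peptide_id} and \code{sequence}.
#' @export
read_peptides <- function(path) {
  first <- readLines(path, n = 1L)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  set <- Biostrings::readBStringSet(path, format = fmt)
  peptides <- data.frame(
    peptide_id = sub("\\s.*$", "", names(set)),
    sequence = toupper(as.character(set)),
    stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  validate_peptides(peptides)
  peptides
}

validate_peptides <- function(peptides) {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptides$sequence) |
    nchar(peptides$sequence) < 3L
  if (any(bad)) {
    stop("Invalid peptide(s) (non-standard residues or length < 3): ",
         paste(peptides$peptide_id[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Peptide search configuration
#'
#' Defaults reproduce the short-peptide protein-BLAST parameter set used for
#' the optional \code{blastp} backend; the canonical \code{exact} backend
#' needs none of them.
#'
#' @param backend \code{"exact"} (canonical) or \code{"blastp"}.
#' @param word_size,gapopen,gapextend,matrix,threshold,comp_based_stats,window_size,evalue
#'   BLASTP tuning parameters (short-peptide preset).
#' @param threads Worker threads for the blastp backend.
#' @return A list of class \code{query_config}.
#' @export
query_config <- function(backend = c("exact", "blastp"), word_size = 3,
                         gapopen = 9, gapextend = 1, matrix = "PAM30",
                         threshold = 16, comp_based_stats = 0,
                         window_size = 15, evalue = 0.05, threads = 1L) {
  structure(list(backend = match.arg(backend), word_size = word_size,
                 gapopen = gapopen, gapextend = gapextend, matrix = matrix,
                 threshold = threshold, comp_based_stats = comp_based_stats,
                 window_size = window_size, evalue = evalue,
                 threads = threads),
            class = "query_config")
}

#' Search peptides against the ORF protein database
#'
#' The canonical \code{exact} backend reports every occurrence of each
#' peptide as a substring of an ORF protein (all offsets, all ORFs, reference
#' and personalized entries alike); this is by construction the set of
#' 100%-identity, full-length matches. The \code{blastp} backend runs
#' protein BLAST with the short-peptide parameter preset and then applies
#' the same identity/length filter; heuristic seeding can miss short exact
#' matches, so it returns a subset of the exact backend.
#'
#' @param peptides Data.frame from [read_peptides()] (peptide_id, sequence).
#' @param db An \code{orf_db}.
#' @param config A [query_config()].
#' @return A data.frame of hits: \code{peptide_id, peptide, orf_id,
#'   protein_offset} (0-based), \code{identity_pct, align_len}.
#' @export
find_peptide_hits <- function(peptides, db, config = query_config()) {
  validate_peptides(peptides)
  if (is.null(db$orfs) || nrow(db$orfs) == 0L) stop("Empty ORF database")
  if (config$backend == "blastp") {
    return(find_peptide_hits_blastp(peptides, db, config))
  }
  proteins <- Biostrings::AAStringSet(db$orfs$protein)
  hits <- lapply(seq_len(nrow(peptides)), function(i) {
    m <- Biostrings::vmatchPattern(peptides$sequence[i], proteins)
    idx <- which(S4Vectors::elementNROWS(m) > 0L)
    if (length(idx) == 0L) return(NULL)
    do.call(rbind, lapply(idx, function(j) {
      starts <- BiocGenerics::start(m[[j]])
      data.frame(peptide_id = peptides$peptide_id[i],
                 peptide = peptides$sequence[i],
                 orf_id = db$orfs$orf_id[j],
                 protein_offset = starts - 1L,
                 identity_pct = 100,
                 align_len = nchar(peptides$sequence[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  out <- if (length(hits)) do.call(rbind, hits) else empty_hits()
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(peptide_id = character(0), peptide = character(0),
             orf_id = character(0), protein_offset = integer(0),
             identity_pct = numeric(0), align_len = integer(0),
             stringsAsFactors = FALSE)
}

# blastp compatibility backend: shells out to makeblastdb/blastp and applies
# the 100%-identity full-length filter to the tabular output.
find_peptide_hits_blastp <- function(peptides, db, config) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stop("blastp backend requires the BLAST+ binaries on PATH")
  }
  wd <- tempfile("blastq")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  dbfa <- file.path(wd, "orfs.faa")
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::AAStringSet(db$orfs$protein),
                    db$orfs$orf_id), dbfa)
  qfa <- file.path(wd, "query.faa")
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::AAStringSet(peptides$sequence),
                    peptides$peptide_id), qfa)
  system2("makeblastdb", c("-in", dbfa, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  outf <- file.path(wd, "hits.tsv")
  system2("blastp", c(
    "-query", qfa, "-db", dbfa, "-out", outf,
    "-word_size", config$word_size, "-gapopen", config$gapopen,
    "-gapextend", config$gapextend, "-matrix", config$matrix,
    "-threshold", config$threshold,
    "-comp_based_stats", config$comp_based_stats,
    "-window_size", config$window_size, "-evalue", config$evalue,
    "-num_threads", config$threads,
    "-outfmt", shQuote("6 qseqid sseqid pident length qstart qend sstart send")),
    stdout = FALSE, stderr = FALSE)
  if (!file.exists(outf) || file.size(outf) == 0L) return(empty_hits())
  tab <- utils::read.table(outf, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("qseqid", "sseqid", "pident",
                                         "length", "qstart", "qend",
                                         "sstart", "send"))
  qlen <- nchar(peptides$sequence)[match(tab$qseqid, peptides$peptide_id)]
  keep <- tab$pident == 100 & tab$length == qlen &
    tab$qstart == 1L & tab$qend == qlen
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) return(empty_hits())
  out <- data.frame(
    peptide_id = tab$qseqid,
    peptide = peptides$sequence[match(tab$qseqid, peptides$peptide_id)],
    orf_id = tab$sseqid,
    protein_offset = tab$sstart - 1L,
    identity_pct = tab$pident,
    align_len = tab$length,
    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Derive genomic fragments from peptide hits
#'
#' For every hit and every genomic placement of the hit ORF, computes the
#' exact genomic interval (3x peptide length) encoding the peptide. On a
#' \code{+} placement \code{[S,E]} the fragment is
#' \code{[S + 3*offset, S + 3*offset + 3L - 1]}; on a \code{-} placement it
#' is \code{[E - 3*(offset+L) + 1, E - 3*offset]}. Each fragment's
#' coding-orientation translation is verified to equal the peptide (for
#' reference-provenance ORFs, against the stored region sequence).
#'
#' @param hits Hit table from [find_peptide_hits()].
#' @param db The \code{orf_db} the hits came from.
#' @return A data.frame of fragments, one row per (hit, placement):
#'   \code{peptide_id, peptide, chrom, start, end, strand, region_id,
#'   orf_id, protein_offset, orf_start, orf_end, provenance}.
#' @export
hit_to_fragment <- function(hits, db) {
  if (nrow(hits) == 0L) return(empty_fragments())
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    orf_idx <- match(hits$orf_id[i], db$orfs$orf_id)
    pl <- db$placements[db$placements$orf_id == hits$orf_id[i], , drop = FALSE]
    if (nrow(pl) == 0L) stop("ORF without placement: ", hits$orf_id[i])
    L <- nchar(hits$peptide[i])
    off <- hits$protein_offset[i]
    fs <- ifelse(pl$strand == "+",
                 pl$start + 3L * off,
                 pl$start + 3L * (nchar(db$orfs$protein[orf_idx]) - off - L))
    fe <- fs + 3L * L - 1L
    if (any(fs < pl$start | fe > pl$end)) {
      stop("Fragment arithmetic escapes ORF placement for ", hits$orf_id[i])
    }
    data.frame(peptide_id = hits$peptide_id[i], peptide = hits$peptide[i],
               chrom = pl$chrom, start = as.integer(fs), end = as.integer(fe),
               strand = pl$strand,
               region_id = db$orfs$region_id[orf_idx],
               orf_id = hits$orf_id[i], protein_offset = off,
               orf_start = pl$start, orf_end = pl$end,
               provenance = db$orfs$provenance[orf_idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  verify_fragment_translation(out, db)
  out
}

empty_fragments <- function() {
  data.frame(peptide_id = character(0), peptide = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), region_id = character(0),
             orf_id = character(0), protein_offset = integer(0),
             orf_start = integer(0), orf_end = integer(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

# Check translate(coding-orientation fragment DNA) == peptide using the
# stored region sequences (reference provenance only; variant fragments
# encode sample alleles).
verify_fragment_translation <- function(fragments, db) {
  ref <- which(fragments$provenance == "reference")
  if (length(ref) == 0L) return(invisible(TRUE))
  dna <- vapply(ref, function(i) {
    region <- db$regions[db$regions$region_id == fragments$region_id[i], ,
                         drop = FALSE]
    d <- region_window_dna(region, fragments$start[i], fragments$end[i])
    if (fragments$strand[i] == "-") revcomp_chr(d) else d
  }, character(1))
  got <- translate_dna_vec(dna)
  bad <- which(got != fragments$peptide[ref])
  if (length(bad) > 0L) {
    i <- ref[bad[1]]
    stop("Fragment translation mismatch for ", fragments$peptide_id[i],
         " at ", fragments$chrom[i], ":", fragments$start[i], "-",
         fragments$end[i], ": got ", got[bad[1]])
  }
  invisible(TRUE)
}

#' Merge duplicate fragments
#'
#' Fragments with identical \code{(peptide_id, chrom, start, end, strand)}
#' merge into one row; their sources (region/ORF/provenance descriptors) are
#' concatenated. Output is sorted by (peptide_id, chrom, start).
#'
#' @param fragments Fragment table from [hit_to_fragment()].
#' @return Merged fragment table with collapsed \code{region_ids, orf_ids,
#'   orf_spans, provenance} columns, an \code{n_sources} count and a
#'   \code{fragment_id} label \code{"chrom:start-end(strand)"}.
#' @export
merge_fragments <- function(fragments) {
  if (nrow(fragments) == 0L) {
    out <- data.frame(peptide_id = character(0), peptide = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      fragment_id = character(0), n_sources = integer(0),
                      region_ids = character(0), orf_ids = character(0),
                      orf_spans = character(0), provenance = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  key <- paste(fragments$peptide_id, fragments$chrom, fragments$start,
               fragments$end, fragments$strand, sep = "\r")
  grp <- split(seq_len(nrow(fragments)), key)
  rows <- lapply(grp, function(idx) {
    f <- fragments[idx, , drop = FALSE]
    data.frame(peptide_id = f$peptide_id[1], peptide = f$peptide[1],
               chrom = f$chrom[1], start = f$start[1], end = f$end[1],
               strand = f$strand[1],
               fragment_id = sprintf("%s:%d-%d(%s)", f$chrom[1], f$start[1],
                                     f$end[1], f$strand[1]),
               n_sources = nrow(f),
               region_ids = paste(f$region_id, collapse = ","),
               orf_ids = paste(f$orf_id, collapse = ","),
               orf_spans = paste(sprintf("%s:%d-%d", f$chrom, f$orf_start,
                                         f$orf_end), collapse = ","),
               provenance = paste(unique(f$provenance), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peptide_id, out$chrom, out$start, out$end,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write merged fragments as a GTF annotation
#'
#' One \code{HERV_fragment} feature line per fragment, 1-based inclusive
#' coordinates, strand column from the fragment, and attributes carrying the
#' peptide id, source region/ORF ids, the whole-ORF genomic span(s), the hit
#' span (the fragment itself) and provenance.
#'
#' @param fragments Merged fragment table from [merge_fragments()].
#' @param path Output GTF path.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(fragments, path) {
  lines <- vapply(seq_len(nrow(fragments)), function(i) {
    f <- fragments[i, ]
    attrs <- sprintf(
      paste0('peptide_id "%s"; peptide "%s"; region_ids "%s"; ',
             'orf_ids "%s"; orf_span "%s"; hit_span "%s:%d-%d"; ',
             'provenance "%s";'),
      f$peptide_id, f$peptide, f$region_ids, f$orf_ids, f$orf_spans,
      f$chrom, f$start, f$end, f$provenance)
    paste(f$chrom, "hervtrace", "HERV_fragment", f$start, f$end, ".",
          f$strand, ".", attrs, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(merge_fragments(empty_fragments()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    attr_of <- function(key) {
      m <- regmatches(p[9], regexpr(sprintf('%s "[^"]*"', key), p[9]))
      sub(sprintf('^%s "(.*)"$', key), "\\1", m)
    }
    data.frame(peptide_id = attr_of("peptide_id"),
               peptide = attr_of("peptide"),
               chrom = p[1], start = as.integer(p[4]), end = as.integer(p[5]),
               strand = p[7],
               fragment_id = sprintf("%s:%s-%s(%s)", p[1], p[4], p[5], p[7]),
               n_sources = length(strsplit(attr_of("orf_ids"), ",")[[1]]),
               region_ids = attr_of("region_ids"),
               orf_ids = attr_of("orf_ids"),
               orf_spans = attr_of("orf_span"),
               provenance = attr_of("provenance"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
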