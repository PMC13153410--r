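#' Read a UCSC chain file
#'
#' Parses the UCSC chain format into an ordered list of alignment blocks
#' mapping source-assembly intervals to target-assembly intervals. Only
#' plus-strand source chains are supported (the format UCSC distributes);
#' minus-strand target chains are converted to plus-strand target
#' coordinates with a strand flip recorded on each block.
#'
#' @param path Chain file path.
#' @param source_assembly,target_assembly Optional assembly tags recorded on
#'   the map (used by [lift_interval()] for bookkeeping).
#' @return An object of class \code{chain_map}: a data.frame of blocks with
#'   columns \code{src_chrom, src_start, src_end, tgt_chrom, tgt_start,
#'   tgt_end, flip} (0-based half-open coordinates internally), sorted by
#'   source position within each chromosome.
#' @export
read_chain <- function(path, source_assembly = NA_character_,
                       target_assembly = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (hdr[1] != "chain") stop("Malformed chain file: expected 'chain' header at line ", i)
    # chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd [id]
    t_name <- hdr[3]; t_strand <- hdr[5]
    t_pos <- as.numeric(hdr[6])
    q_name <- hdr[8]; q_size <- as.numeric(hdr[9]); q_strand <- hdr[10]
    q_pos <- as.numeric(hdr[11])
    if (t_strand != "+") stop("Only '+' source strand chains are supported")
    i <- i + 1L
    repeat {
      parts <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      size <- parts[1]
      ss <- t_pos; se <- t_pos + size
      qs <- q_pos; qe <- q_pos + size
      if (q_strand == "-") {
        blocks[[length(blocks) + 1L]] <- data.frame(
          src_chrom = t_name, src_start = ss, src_end = se,
          tgt_chrom = q_name, tgt_start = q_size - qe, tgt_end = q_size - qs,
          flip = TRUE, stringsAsFactors = FALSE)
      } else {
        blocks[[length(blocks) + 1L]] <- data.frame(
          src_chrom = t_name, src_start = ss, src_end = se,
          tgt_chrom = q_name, tgt_start = qs, tgt_end = qe,
          flip = FALSE, stringsAsFactors = FALSE)
      }
      if (length(parts) == 1L) { i <- i + 1L; break }
      t_pos <- se + parts[2]
      q_pos <- qe + parts[3]
      i <- i + 1L
    }
  }
  blocks <- do.call(rbind, blocks)
  blocks <- blocks[order(blocks$src_chrom, blocks$src_start), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(blocks,
            source_assembly = source_assembly,
            target_assembly = target_assembly,
            class = c("chain_map", "data.frame"))
}

#' Lift an interval to another assembly through a chain map
#'
#' An interval lifts only if it is contained in a single chain block (mapped
#' contiguously with no split and no gap inside it); its length is then
#' preserved exactly. Intervals straddling block boundaries are rejected with
#' reason \code{"split"}; intervals with no covering chain with reason
#' \code{"unmapped"}. The strand is composed with the chain's orientation.
#'
#' @param placement A one-row data.frame with \code{chrom, start, end,
#'   strand} (1-based inclusive) and optionally \code{assembly}.
#' @param chain_map A \code{chain_map} from [read_chain()].
#' @return A list with \code{status} (\code{"lifted"}, \code{"split"} or
#'   \code{"unmapped"}) and, when lifted, \code{placement}: the interval in
#'   target coordinates.
#' @export
lift_interval <- function(placement, chain_map) {
  src_asm <- attr(chain_map, "source_assembly")
  if (!is.na(src_asm) && !is.null(placement$assembly) &&
      !is.na(placement$assembly) && placement$assembly != src_asm) {
    stop("Placement assembly (", placement$assembly,
         ") does not match chain source assembly (", src_asm, ")")
  }
  s0 <- placement$start - 1L   # to 0-based half-open
  e0 <- placement$end
  bl <- chain_map[chain_map$src_chrom == placement$chrom, , drop = FALSE]
  contained <- which(bl$src_start <= s0 & e0 <= bl$src_end)
  if (length(contained) >= 1L) {
    b <- bl[contained[1L], ]
    if (b$flip) {
      ts0 <- b$tgt_start + (b$src_end - e0)
      te0 <- b$tgt_start + (b$src_end - s0)
      strand <- flip_strand(placement$strand)
    } else {
      ts0 <- b$tgt_start + (s0 - b$src_start)
      te0 <- b$tgt_start + (e0 - b$src_start)
      strand <- placement$strand
    }
    out <- data.frame(chrom = b$tgt_chrom, start = as.integer(ts0 + 1L),
                      end = as.integer(te0), strand = strand,
                      assembly = attr(chain_map, "target_assembly"),
                      stringsAsFactors = FALSE)
    return(list(status = "lifted", placement = out))
  }
  touches <- any(bl$src_start < e0 & s0 < bl$src_end)
  list(status = if (touches) "split" else "unmapped", placement = NULL)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Lift every placement of an ORF database
#'
#' Applies [lift_interval()] to each placement. Successfully lifted
#' placements are rewritten in target coordinates; rejected placements are
#' dropped from the database and returned in a rejection table (never
#' silently discarded).
#'
#' @param db An \code{orf_db}.
#' @param chain_map A \code{chain_map}.
#' @return A list: \code{db} (lifted database; regions keep their source
#'   coordinates, placements carry the target assembly tag) and
#'   \code{rejections} (orf_id, chrom, start, end, reason).
#' @export
lift_database <- function(db, chain_map) {
  pl <- db$placements
  status <- character(nrow(pl))
  lifted <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    res <- lift_interval(pl[i, , drop = FALSE], chain_map)
    status[i] <- res$status
    lifted[[i]] <- res$placement
  }
  ok <- status == "lifted"
  new_pl <- pl
  if (any(ok)) {
    repl <- do.call(rbind, lifted[ok])
    new_pl$chrom[ok] <- repl$chrom
    new_pl$start[ok] <- repl$start
    new_pl$end[ok] <- repl$end
    new_pl$strand[ok] <- repl$strand
    new_pl$assembly[ok] <- repl$assembly
  }
  new_db <- db
  new_db$placements <- new_pl[ok, , drop = FALSE]
  new_db$assembly <- attr(chain_map, "target_assembly")
  rejections <- cbind(pl[!ok, c("orf_id", "chrom", "start", "end"),
                         drop = FALSE],
                      reason = status[!ok])
  rownames(rejections) <- NULL
  list(db = new_db, rejections = rejections)
}
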