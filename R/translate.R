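#' Six-frame translation of a DNA sequence
#'
#' Translates a DNA sequence in all six reading frames with the standard
#' genetic code. Frames \code{+1/+2/+3} read the given sequence at offsets
#' 0/1/2; frames \code{-1/-2/-3} read its reverse complement at offsets 0/1/2.
#' Stop codons are retained as \code{'*'}; any codon containing \code{N}
#' translates to \code{'X'}. A trailing partial codon (1-2 bases) of a frame
#' is ignored.
#'
#' @param dna A single DNA string over \code{A,C,G,T,N} (case-insensitive),
#'   or a [Biostrings::DNAString].
#' @return A named character vector of length 6 with names
#'   \code{"+1","+2","+3","-1","-2","-3"}.
#' @examples
#' six_frame_translate("ATGAAATAG")[["+1"]]  # "MK*"
#' @export
six_frame_translate <- function(dna) {
  dna <- normalize_dna(dna)
  rc <- revcomp_chr(dna)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  srcs <- c(dna, substring(dna, 2L), substring(dna, 3L),
            rc, substring(rc, 2L), substring(rc, 3L))
  stats::setNames(translate_dna_vec(srcs), frames)
}

# Vectorized frame-1 translation of plain character DNA; drops trailing
# partial codons; N-containing codons become 'X'.
translate_dna_vec <- function(dna) {
  n <- (nchar(dna) %/% 3L) * 3L
  out <- character(length(dna))
  trimmed <- substr(dna, 1L, n)
  # the fuzzy-codon path rebuilds a lookup table per call; only take it for
  # sequences that actually contain N
  has_n <- grepl("N", trimmed, fixed = TRUE)
  plain <- which(n > 0L & !has_n)
  fuzzy <- which(n > 0L & has_n)
  if (length(plain) > 0L) {
    out[plain] <- as.character(
      Biostrings::translate(Biostrings::DNAStringSet(trimmed[plain]),
                            no.init.codon = TRUE))
  }
  if (length(fuzzy) > 0L) {
    out[fuzzy] <- as.character(
      Biostrings::translate(Biostrings::DNAStringSet(trimmed[fuzzy]),
                            if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  out
}

# Validate and uppercase a DNA string; only A,C,G,T,N accepted.
normalize_dna <- function(dna) {
  if (methods::is(dna, "DNAString") || methods::is(dna, "BString")) {
    dna <- as.character(dna)
  }
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", dna), "")[[1]])
    stop("DNA sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  dna
}

#' Extract open reading frames from one frame translation
#'
#' ORFs are the maximal stop-free substrings of a frame translation, i.e. the
#' stretches between \code{'*'} symbols (and the sequence ends). Each ORF is
#' returned with its 0-based amino-acid offset within the frame translation.
#'
#' @param frame_translation Amino-acid string, possibly containing \code{'*'}.
#' @param min_len Minimum ORF length in residues to retain (default 1).
#' @return A data.frame with columns \code{protein} and \code{offset}.
#' @examples
#' extract_orfs("MK*GILLPQPPK")
#' @export
extract_orfs <- function(frame_translation, min_len = 1L) {
  stopifnot(is.character(frame_translation), length(frame_translation) == 1L,
            min_len >= 1L)
  if (nchar(frame_translation) == 0L) {
    return(data.frame(protein = character(0), offset = integer(0)))
  }
  pieces <- strsplit(frame_translation, "*", fixed = TRUE)[[1]]
  lens <- nchar(pieces)
  # offset of piece i = cumulative length of previous pieces + one '*' each
  offs <- cumsum(c(0L, lens[-length(lens)] + 1L))
  keep <- lens >= min_len
  data.frame(protein = pieces[keep], offset = offs[keep],
             stringsAsFactors = FALSE)
}

# Base-complement reverse complement for plain character strings.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}
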