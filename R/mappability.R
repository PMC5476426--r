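#' Theoretical mappability from k-mer uniqueness
#'
#' Approximates a read-mapping mappability track by substring uniqueness:
#' reads of length `read_length` are taken every `step` bp along each
#' chromosome and scored 1 when that sequence occurs exactly once in the
#' combined genome (counting both strands), else 0. This is a proxy for the
#' full procedure of remapping simulated reads with an aligner and requiring
#' high mapping quality at the correct location; it captures exact-repeat
#' structure but not mismatch-tolerant ambiguity.
#'
#' Windows containing non-ACGT characters are scored 0 and still counted.
#'
#' @param sequences named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param read_length read length in bp (80 for the interspecific hybrids,
#'   150 for the intraspecific one).
#' @param step window spacing in bp (default 10).
#' @return data frame with `chrom`, `start` (0-based window start), `score`
#'   (0/1 uniqueness).
#' @seealso [bin_mappability()] to average scores per genomic bin.
#' @export
kmer_mappability <- function(sequences, read_length, step = 10) {
  seqs <- as_dna_character(sequences)
  if (read_length > min(nchar(seqs)))
    stop("read_length must not exceed the shortest chromosome")
  canon <- function(s) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
    ifelse(s <= rc, s, rc)
  }
  # occurrence counts of every read_length-mer at every position, canonical strand
  all_kmers <- unlist(lapply(seqs, function(s) {
    starts <- seq_len(nchar(s) - read_length + 1L)
    substring(s, starts, starts + read_length - 1L)
  }), use.names = FALSE)
  clean <- grepl("^[ACGT]+$", all_kmers)
  counts <- table(canon(all_kmers[clean]))

  out <- lapply(names(seqs), function(cn) {
    s <- seqs[[cn]]
    starts <- seq(1L, nchar(s) - read_length + 1L, by = step)
    w <- substring(s, starts, starts + read_length - 1L)
    ok <- grepl("^[ACGT]+$", w)
    score <- integer(length(w))
    score[ok] <- as.integer(counts[canon(w[ok])] == 1L)
    data.frame(chrom = cn, start = starts - 1L, score = score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average mappability scores per genomic bin
#'
#' @param scores output of [kmer_mappability()].
#' @param index a `bin_index`.
#' @return the `index` with an added `mappability` column (mean window score
#'   of windows starting in the bin; `NaN` for bins with no window).
#' @export
bin_mappability <- function(scores, index) {
  b <- bin_of_position(index, scores$chrom, scores$start)
  m <- tapply(scores$score, factor(b, levels = index$bin), mean)
  index$mappability <- as.numeric(m)
  index
}

as_dna_character <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), names(ss))
  } else if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences) || is.null(names(sequences)))
    stop("sequences must be a named character vector, DNAStringSet, or FASTA path")
  toupper(sequences)
}
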