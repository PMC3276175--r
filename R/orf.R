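## ORF scanning inside candidate ncRNAs. Standard genetic code, ATG starts
## by default; an ORF is the first start codon of a stop-delimited segment
## through its in-frame stop (non-nested per frame). aa_length counts the
## initial Met through the residue before the stop, so a 49-aa ORF spans
## 150 nt including its stop codon.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames on one strand
#'
#' Scans the given sequence only (supply the reverse complement for minus-
#' strand candidates): per frame, each stop-delimited segment contributes at
#' most one ORF, from its first start codon to the in-frame stop. Codons
#' containing `N` never match start or stop codons.
#'
#' @param seq Nucleotide string over `A,C,G,T,N`.
#' @param min_aa Minimum amino-acid length (default 20), counting the
#'   initial Met and excluding the stop.
#' @param start_codons Start codon set (default `"ATG"` only).
#' @return `data.frame` with `offset_start`, `offset_stop` (1-based within
#'   `seq`, first base of the start codon to last base of the stop codon),
#'   `aa_length` and `frame` (1-3), sorted by `offset_start`.
#' @export
find_orfs <- function(seq, min_aa = 20, start_codons = "ATG") {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over {A,C,G,T,N}")
  n <- nchar(seq)
  out <- list()
  for (frame in 1:3) {
    ncod <- (n - frame + 1L) %/% 3L
    if (ncod < 2L) next
    pos <- frame + 3L * (seq_len(ncod) - 1L)
    codons <- substring(seq, pos, pos + 2L)
    is_start <- codons %in% start_codons
    is_stop <- codons %in% STOP_CODONS
    seg <- cumsum(c(FALSE, head(is_stop, -1L))) # segment id per codon
    for (s in unique(seg[is_start])) {
      in_seg <- which(seg == s)
      stop_i <- in_seg[is_stop[in_seg]]
      if (!length(stop_i)) next # runs off the end: not an ORF
      start_i <- in_seg[is_start[in_seg]][1]
      if (start_i >= stop_i) next
      aa <- stop_i - start_i
      if (aa < min_aa) next
      out[[length(out) + 1L]] <- data.frame(
        offset_start = pos[start_i], offset_stop = pos[stop_i] + 2L,
        aa_length = aa, frame = frame)
    }
  }
  if (!length(out))
    return(data.frame(offset_start = integer(), offset_stop = integer(),
                      aa_length = integer(), frame = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$offset_start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Longest ORF inside a candidate interval
#'
#' Extracts the candidate's genomic interval, reverse-complements it for
#' minus-strand candidates, and returns the maximal-length ORF (ties broken
#' by smallest offset).
#'
#' @param genome A [plastome()] with residues.
#' @param candidate One-row candidate data.frame (`start`, `stop`,
#'   `strand`).
#' @param min_aa Minimum amino-acid length (default 20).
#' @param start_codons Start codon set (default `"ATG"`).
#' @return One-row ORF `data.frame` as from [find_orfs()] (offsets within
#'   the strand-oriented candidate sequence), or `NULL` when none.
#' @export
longest_orf_in_candidate <- function(genome, candidate, min_aa = 20,
                                     start_codons = "ATG") {
  stopifnot(inherits(genome, "plastome"))
  if (is.null(genome$residues))
    stop("genome has no residues; ORF scanning needs sequence")
  if (candidate$stop > genome$length || candidate$start < 1L)
    stop("candidate outside the genome")
  seq <- substr(genome$residues, candidate$start, candidate$stop)
  if (candidate$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  orfs <- find_orfs(seq, min_aa = min_aa, start_codons = start_codons)
  if (!nrow(orfs)) return(NULL)
  orfs[order(-orfs$aa_length, orfs$offset_start), ][1, ]
}

#' Translate an ORF to its peptide
#'
#' Convenience accessor used for reports and for checking that returned
#' ORFs re-translate without internal stops.
#'
#' @param seq The (strand-oriented) nucleotide sequence the ORF was found
#'   in.
#' @param orf One-row ORF record from [find_orfs()].
#' @return Amino-acid string including the initial `M`, excluding the stop.
#' @export
orf_peptide <- function(seq, orf) {
  nt <- substr(as.character(seq), orf$offset_start, orf$offset_stop - 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}
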