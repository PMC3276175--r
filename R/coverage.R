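## Stranded coverage: read placements -> per-base depth and read-start
## tracks. The library protocol is directional, so a placement's strand is
## the transcript strand. Doubly-placed reads (inverted repeat, aligner
## accepts up to two locations) carry full weight at both placements by
## default; `multi_weight = 0.5` halves them.

#' Construct a placement table
#'
#' @param read_id,start,stop,strand Parallel vectors describing placements
#'   (1-based inclusive coordinates, strand `+`/`-`).
#' @return A `data.frame` with columns `read_id`, `start`, `stop`, `strand`,
#'   `n_placements`, where `n_placements` counts placements sharing a
#'   `read_id` (at most 2, mirroring the aligner setting).
#' @export
placements <- function(read_id, start, stop, strand) {
  df <- data.frame(read_id = as.character(read_id),
                   start = as.integer(start), stop = as.integer(stop),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start > df$stop))
      stop("placement start > stop for read ",
           df$read_id[which(df$start > df$stop)[1]])
    if (!all(df$strand %in% c("+", "-")))
      stop("placement strand must be '+' or '-'")
    n <- table(df$read_id)
    if (any(n > 2L))
      stop("read placed more than twice: ",
           paste(head(names(n)[n > 2L], 3), collapse = ", "))
    df$n_placements <- as.integer(n[df$read_id])
  } else df$n_placements <- integer()
  df
}

#' Load strand-specific read placements
#'
#' Reads either the 5-column tabular placement format (`read_id`, `start`,
#' `stop`, `strand`, `n_placements`; header optional, `n_placements`
#' recomputed) or a SAM/BAM file (mapped records only; strand from the
#' alignment flag; reference span from the CIGAR). Unmapped records are
#' skipped and counted in the `skipped_unmapped` attribute.
#'
#' @param path Input file; `.sam`/`.bam` are routed through
#'   Rsamtools/GenomicAlignments, anything else is read as tabular text.
#' @return A placement `data.frame` as from [placements()].
#' @export
load_placements <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) return(load_placements_sam(path))
  first <- readLines(path, n = 1L)
  header <- length(first) > 0 && grepl("read_id", first)
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L && ncol(tab) < 4L)
    return(placements(character(), integer(), integer(), character()))
  if (!header) names(tab)[1:4] <- c("read_id", "start", "stop", "strand")
  placements(tab$read_id, tab$start, tab$stop, tab$strand)
}

load_placements_sam <- function(path) {
  for (p in c("Rsamtools", "GenomicAlignments"))
    if (!requireNamespace(p, quietly = TRUE))
      stop("SAM/BAM input requires the ", p, " package")
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  n_total <- Rsamtools::countBam(path)$records
  aln <- GenomicAlignments::readGAlignments(path, use.names = TRUE)
  out <- placements(names(aln),
                    GenomicAlignments::start(aln),
                    GenomicAlignments::end(aln),
                    as.character(GenomicAlignments::strand(aln)))
  attr(out, "skipped_unmapped") <- n_total - length(aln)
  out
}

#' Write placements in the tabular placement format
#'
#' @param pl Placement `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_placements <- function(pl, path) {
  write.table(pl[, c("read_id", "start", "stop", "strand", "n_placements")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build stranded coverage from placements
#'
#' Each placement adds 1 (or `multi_weight` for doubly-placed reads) to the
#' depth at every covered base on its strand and to the start track at its
#' start base.
#'
#' @param pl Placement `data.frame` from [placements()]/[load_placements()].
#' @param genome_length Genome length in nt.
#' @param multi_weight Weight for each placement of a doubly-placed read
#'   (default 1: full weight at both inverted-repeat copies).
#' @return An object of class `stranded_coverage`: per-strand `depth` and
#'   `starts` numeric tracks of length `genome_length`, plus the total
#'   placement weight `n_placements`.
#' @export
coverage_from_placements <- function(pl, genome_length, multi_weight = 1) {
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length >= 1L)
  if (nrow(pl)) {
    bad <- pl$start < 1L | pl$stop > genome_length
    if (any(bad))
      stop("placement out of range for read ", pl$read_id[which(bad)[1]])
  }
  w <- ifelse(pl$n_placements == 2L, multi_weight, 1)
  one <- function(sel) {
    # difference-array: +w at start, -w past stop, cumsum gives depth;
    # weights take at most two values, so group placements by weight
    d <- numeric(genome_length + 1L)
    starts <- numeric(genome_length)
    for (iv in split(which(sel), w[sel])) {
      wt <- w[iv[1]]
      d <- d + wt * (tabulate(pl$start[iv], genome_length + 1L) -
                     tabulate(pl$stop[iv] + 1L, genome_length + 1L))
      starts <- starts + wt * tabulate(pl$start[iv], genome_length)
    }
    list(depth = cumsum(d[seq_len(genome_length)]), starts = starts)
  }
  plus <- one(pl$strand == "+")
  minus <- one(pl$strand == "-")
  structure(list(genome_length = genome_length,
                 depth = list("+" = plus$depth, "-" = minus$depth),
                 starts = list("+" = plus$starts, "-" = minus$starts),
                 n_placements = sum(w)),
            class = "stranded_coverage")
}

#' Construct stranded coverage from raw tracks
#'
#' Mostly useful for tests and for bedGraph-derived coverage, which has no
#' start tracks (operations needing them then refuse with an error).
#'
#' @param depth_plus,depth_minus Non-negative numeric depth tracks.
#' @param starts_plus,starts_minus Optional read-start tracks.
#' @return A `stranded_coverage`.
#' @export
stranded_coverage <- function(depth_plus, depth_minus,
                              starts_plus = NULL, starts_minus = NULL) {
  stopifnot(length(depth_plus) == length(depth_minus),
            all(depth_plus >= 0), all(depth_minus >= 0))
  has_starts <- !is.null(starts_plus) && !is.null(starts_minus)
  if (has_starts)
    stopifnot(length(starts_plus) == length(depth_plus),
              length(starts_minus) == length(depth_plus))
  structure(list(genome_length = length(depth_plus),
                 depth = list("+" = as.numeric(depth_plus),
                              "-" = as.numeric(depth_minus)),
                 starts = if (has_starts)
                   list("+" = as.numeric(starts_plus),
                        "-" = as.numeric(starts_minus)) else NULL,
                 n_placements = if (has_starts)
                   sum(starts_plus) + sum(starts_minus) else NA_real_),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat("<stranded_coverage>", x$genome_length, "nt;",
      if (is.null(x$starts)) "depth only (no start tracks);"
      else paste0(format(x$n_placements, big.mark = ","), " placements;"),
      "max depth +:", max(x$depth[["+"]]), "-:", max(x$depth[["-"]]), "\n")
  invisible(x)
}

check_interval <- function(cov, start, stop, strand) {
  stopifnot(inherits(cov, "stranded_coverage"))
  if (start > stop) stop("invalid interval: start > stop")
  if (start < 1L || stop > cov$genome_length)
    stop("interval outside [1, genome_length]")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
}

#' Count read starts in an interval
#'
#' Sum of the strand's read-start track over `[start, stop]` — the paper's
#' transcript-abundance estimator ("binning reads according to their start
#' position").
#'
#' @param cov A `stranded_coverage` with start tracks.
#' @param start,stop Interval, 1-based inclusive.
#' @param strand `"+"` or `"-"`.
#' @return Numeric count (weighted if `multi_weight` was used).
#' @export
read_start_count <- function(cov, start, stop, strand) {
  check_interval(cov, start, stop, strand)
  if (is.null(cov$starts))
    stop("coverage has no read-start tracks (bedGraph-derived input?); ",
         "read_start_count needs placements")
  sum(cov$starts[[strand]][start:stop])
}

#' Fraction of the genome covered at a minimum depth
#'
#' @param cov A `stranded_coverage`.
#' @param strand `"+"` or `"-"`.
#' @param min_depth Minimum depth (>= 1).
#' @return Fraction in `[0, 1]` of bases with depth >= `min_depth`.
#' @export
covered_fraction <- function(cov, strand, min_depth = 1) {
  stopifnot(inherits(cov, "stranded_coverage"), min_depth >= 1)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  mean(cov$depth[[strand]] >= min_depth)
}

#' Read stranded coverage from a pair of bedGraph files
#'
#' bedGraph is 0-based half-open; tracks are converted to 1-based per-base
#' depth. The result carries no read-start tracks.
#'
#' @param path_plus,path_minus bedGraph file per strand.
#' @param genome_length Genome length in nt.
#' @return A `stranded_coverage` without start tracks.
#' @export
read_bedgraph_coverage <- function(path_plus, path_minus, genome_length) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("bedGraph input requires the rtracklayer package")
  one <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    depth <- numeric(genome_length)
    if (length(gr)) {
      if (max(GenomicRanges::end(gr)) > genome_length)
        stop("bedGraph interval beyond genome length in ", path)
      for (i in seq_along(gr))
        depth[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
          gr$score[i]
    }
    depth
  }
  stranded_coverage(one(path_plus), one(path_minus))
}

#' Write stranded coverage as one bedGraph file per strand
#'
#' @param cov A `stranded_coverage`.
#' @param path_plus,path_minus Output files.
#' @param seqname Sequence name for the bedGraph records.
#' @return Invisibly, `c(path_plus, path_minus)`.
#' @export
write_bedgraph_coverage <- function(cov, path_plus, path_minus,
                                    seqname = "plastome") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("bedGraph output requires the rtracklayer package")
  one <- function(depth, path) {
    r <- rle(depth)
    stop_ <- cumsum(r$lengths)
    start_ <- stop_ - r$lengths + 1L
    keep <- r$values != 0
    gr <- GenomicRanges::GRanges(seqname,
                                 IRanges::IRanges(start_[keep], stop_[keep]),
                                 score = r$values[keep])
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  one(cov$depth[["+"]], path_plus)
  one(cov$depth[["-"]], path_minus)
  invisible(c(path_plus, path_minus))
}
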