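## Classification of called candidates against the gene annotation:
## antisense (>= 1 nt complementarity to a gene or intron on the opposite
## strand) wins over everything; otherwise intergenic if the candidate falls
## inside a transcription cluster's span without same-strand gene overlap;
## otherwise a rejection record (sense-transcript fragment / unassigned),
## which is data, not an error.

#' Classify candidates as antisense or intergenic
#'
#' For each candidate: (1) if it overlaps at least one opposite-strand gene
#' or intron it is `antisense`, with all such features as targets; (2)
#' otherwise, if it lies within the genomic span of a cluster (features
#' sharing a `cluster_id`) and overlaps no same-strand non-intron gene, it
#' is `intergenic`, with the flanking cluster genes as targets; (3)
#' otherwise it is `rejected` with reason `same_strand_overlap` (likely a
#' fragment of a known sense transcript, excluded by design) or
#' `unassigned`.
#'
#' The principal target (used for naming and the category summary) is the
#' opposite-strand feature with the largest overlap, ties broken by smaller
#' start — except that a candidate wholly contained in an opposite-strand
#' intron takes that intron as principal target (an intron never wins on
#' raw overlap, lying inside its parent gene's span). Pairing-region flags
#' are computed against the principal target with [pairing_region()].
#'
#' @param candidates An `ncrna_candidates` data.frame.
#' @param ann A `plastid_annotation`.
#' @param window_5p,window_3p Terminus windows (nt) for [pairing_region()]
#'   (default 25 each).
#' @return A data.frame of class `classified_ncrnas`: the candidate columns
#'   plus `ncrna_class` (`antisense` / `intergenic` / `rejected`),
#'   `targets` (comma-separated feature names), `region_flags`
#'   (comma-separated subset of five_prime, three_prime, internal),
#'   `principal_target`, `target_category`, `reject_reason` and `name`
#'   (systematic name from [assign_names()]).
#' @export
classify_candidates <- function(candidates, ann,
                                window_5p = 25, window_3p = 25) {
  stopifnot(inherits(ann, "plastid_annotation"))
  n <- nrow(candidates)
  cls <- character(n); targets <- character(n); flags <- character(n)
  principal <- character(n); categ <- character(n); reason <- character(n)
  feats <- ann$features
  clusters <- split(seq_len(nrow(feats)), feats$cluster_id)
  for (i in seq_len(n)) {
    cstart <- candidates$start[i]; cstop <- candidates$stop[i]
    cstrand <- candidates$strand[i]
    opp <- features_overlapping(ann, cstart, cstop,
                                paste0("opposite-of:", cstrand))
    if (nrow(opp)) {
      cls[i] <- "antisense"
      targets[i] <- paste(opp$name, collapse = ",")
      # an intron always lies within its parent gene's span, so it can
      # never win on overlap; a candidate contained in an intron is
      # "antisense to the intron" and the intron is its principal target
      within_intron <- opp$kind == "intron" & opp$start <= cstart &
        opp$stop >= cstop
      pool <- if (any(within_intron))
        opp[within_intron, , drop = FALSE] else opp
      ov <- pmin(cstop, pool$stop) - pmax(cstart, pool$start) + 1L
      p <- pool[order(-ov, pool$start), , drop = FALSE][1, ]
      principal[i] <- p$name
      categ[i] <- p$category
      flags[i] <- paste(pairing_region(cstart, cstop, cstrand,
                                       p$start, p$stop, p$strand,
                                       window_5p, window_3p),
                        collapse = ",")
      next
    }
    same <- features_overlapping(ann, cstart, cstop,
                                 paste0("same:", cstrand))
    same_gene <- same[same$kind != "intron", , drop = FALSE]
    if (nrow(same_gene)) {
      cls[i] <- "rejected"; reason[i] <- "same_strand_overlap"
      next
    }
    host <- NULL
    for (cid in names(clusters)) {
      if (cid == "NA" || is.na(cid)) next
      idx <- clusters[[cid]]
      if (cstart >= min(feats$start[idx]) && cstop <= max(feats$stop[idx])) {
        host <- idx; break
      }
    }
    if (!is.null(host)) {
      cf <- feats[host, , drop = FALSE]
      left <- cf[cf$stop < cstart, , drop = FALSE]
      right <- cf[cf$start > cstop, , drop = FALSE]
      flank <- rbind(if (nrow(left)) left[which.max(left$stop), ],
                     if (nrow(right)) right[which.min(right$start), ])
      cls[i] <- "intergenic"
      targets[i] <- paste(flank$name, collapse = ",")
      principal[i] <- flank$name[1]
      categ[i] <- flank$category[1]
    } else {
      cls[i] <- "rejected"; reason[i] <- "unassigned"
    }
  }
  out <- candidates
  out$ncrna_class <- cls
  out$targets <- targets
  out$region_flags <- flags
  out$principal_target <- principal
  out$target_category <- categ
  out$reject_reason <- reason
  out <- assign_names(out)
  class(out) <- c("classified_ncrnas", class(candidates))
  out
}

#' Pairing region of a candidate relative to an opposite-strand gene
#'
#' Orientation-aware terminus windows: the gene's 5' terminal base is its
#' `start` on the + strand and its `stop` on the - strand. `five_prime` is
#' flagged when the candidate overlaps `[5' base - window, 5' base +
#' window]`, `three_prime` analogously; `internal` when the candidate
#' overlaps the gene body but neither terminus window. A candidate spanning
#' both termini gets both flags.
#'
#' @param cstart,cstop,cstrand Candidate interval and strand.
#' @param gstart,gstop,gstrand Gene interval and strand (must be opposite).
#' @param window_5p,window_3p Window half-widths in nt (>= 0).
#' @return Character vector subset of
#'   `c("five_prime", "three_prime", "internal")`.
#' @export
pairing_region <- function(cstart, cstop, cstrand, gstart, gstop, gstrand,
                           window_5p = 25, window_3p = 25) {
  if (cstrand == gstrand)
    stop("pairing_region: gene must be on the strand opposite the candidate")
  stopifnot(window_5p >= 0, window_3p >= 0)
  p5 <- if (gstrand == "+") gstart else gstop
  p3 <- if (gstrand == "+") gstop else gstart
  hit <- function(center, w) cstop >= center - w && cstart <= center + w
  flags <- character()
  if (hit(p5, window_5p)) flags <- c(flags, "five_prime")
  if (hit(p3, window_3p)) flags <- c(flags, "three_prime")
  if (!length(flags) && cstop >= gstart && cstart <= gstop)
    flags <- "internal"
  flags
}

#' Assign systematic names to classified candidates
#'
#' Antisense to gene X gives `as-X`; antisense to X's intron gives `as-Xi`;
#' intergenic between X and Y gives `nc-X-Yint`. When exactly one terminus
#' window is hit, a `-5p` / `-3p` suffix marks which part of the coding
#' region the candidate complements. Candidates sharing a base name then
#' receive ordinal suffixes `-1`, `-2`, ... in genomic order. Rejected
#' candidates keep their id as name.
#'
#' @param classified Output of [classify_candidates()] (called for you by
#'   it; exported for re-naming after manual edits).
#' @return The input with a `name` column filled.
#' @export
assign_names <- function(classified) {
  n <- nrow(classified)
  base <- character(n)
  for (i in seq_len(n)) {
    if (classified$ncrna_class[i] == "antisense") {
      tgt <- classified$principal_target[i]
      # intron features are named <gene>i by convention upstream; keep as-is
      nm <- paste0("as-", tgt)
      fl <- strsplit(classified$region_flags[i], ",")[[1]]
      term <- intersect(fl, c("five_prime", "three_prime"))
      if (length(term) == 1L)
        nm <- paste0(nm, if (term == "five_prime") "-5p" else "-3p")
      base[i] <- nm
    } else if (classified$ncrna_class[i] == "intergenic") {
      tg <- strsplit(classified$targets[i], ",")[[1]]
      base[i] <- paste0("nc-", paste(tg, collapse = "-"), "int")
    } else {
      base[i] <- classified$id[i]
    }
  }
  name <- base
  ord <- order(classified$start, classified$stop)
  for (b in unique(base[duplicated(base)])) {
    idx <- ord[base[ord] == b]
    name[idx] <- paste0(b, "-", seq_along(idx))
  }
  if (anyDuplicated(name))
    stop("internal error: name collision after suffixing")
  classified$name <- name
  classified
}

#' Summarise antisense candidates by target-gene category
#'
#' @param classified Output of [classify_candidates()].
#' @return `data.frame` with `category`, `count` and `fraction` (fractions
#'   sum to 1 over antisense candidates); empty for no antisense input.
#' @export
category_summary <- function(classified) {
  anti <- classified[classified$ncrna_class == "antisense", , drop = FALSE]
  if (!nrow(anti))
    return(data.frame(category = character(), count = integer(),
                      fraction = numeric()))
  tab <- table(anti$target_category)
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / nrow(anti),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export classified candidates as GFF3 and TSV
#'
#' @param classified Output of [classify_candidates()].
#' @param path Output file.
#' @param seqname Sequence name.
#' @return `path`, invisibly.
#' @export
write_classified_gff3 <- function(classified, path, seqname = "plastome") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 output requires the rtracklayer package")
  keep <- classified$ncrna_class != "rejected"
  cc <- classified[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = seqname, ranges = IRanges::IRanges(cc$start, cc$stop),
    strand = cc$strand, type = "ncRNA", source = "plastidnc",
    ID = cc$name, class = cc$ncrna_class, targets = cc$targets,
    flags = cc$region_flags)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_classified_gff3
#' @export
write_classified_tsv <- function(classified, path) {
  cols <- c("name", "start", "stop", "strand", "ncrna_class", "targets",
            "region_flags", "target_category", "end_source",
            "trigger_genotypes", "reject_reason")
  write.table(classified[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
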