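## Genotype comparison: read-start abundance per candidate, counts per
## million (cpm), pseudocounted fold changes, genotype-specific candidate
## sets, and validation rate by coverage bin.

#' Quantify candidates per genotype by read-start binning
#'
#' Raw counts are read starts within the candidate interval on its strand;
#' cpm normalises by the genotype's total placements; the fold change is
#' `(cpm_treatment + eps) / (cpm_reference + eps)`.
#'
#' @param candidates An `ncrna_candidates` (or classified) data.frame.
#' @param coverage_by_genotype Named list of `stranded_coverage` with start
#'   tracks.
#' @param reference,treatment Genotype names for the fold change (defaults:
#'   first and second coverage entries, conventionally WT and the mutant).
#' @param pseudocount Pseudocount in cpm units (default 0.5) keeping
#'   mutant-only species finite.
#' @return `data.frame` with `candidate_id`, per-genotype `count_<g>` and
#'   `cpm_<g>` columns, and `fold_change`.
#' @export
quantify_candidates <- function(candidates, coverage_by_genotype,
                                reference = names(coverage_by_genotype)[1],
                                treatment = names(coverage_by_genotype)[2],
                                pseudocount = 0.5) {
  genos <- names(coverage_by_genotype)
  stopifnot(reference %in% genos, treatment %in% genos, pseudocount >= 0)
  for (g in genos)
    if (is.null(coverage_by_genotype[[g]]$starts))
      stop("coverage for ", g, " has no read-start tracks; ",
           "quantification needs placement-derived coverage")
  out <- data.frame(candidate_id = candidates$id,
                    stringsAsFactors = FALSE)
  for (g in genos) {
    cov <- coverage_by_genotype[[g]]
    raw <- vapply(seq_len(nrow(candidates)), function(i)
      read_start_count(cov, candidates$start[i], candidates$stop[i],
                       candidates$strand[i]), numeric(1))
    out[[paste0("count_", g)]] <- raw
    out[[paste0("cpm_", g)]] <- raw * 1e6 / cov$n_placements
  }
  out$fold_change <- (out[[paste0("cpm_", treatment)]] + pseudocount) /
    (out[[paste0("cpm_", reference)]] + pseudocount)
  out
}

#' Pooled antisense abundance ratio between genotypes
#'
#' Ratio of library-size-normalised total read-start counts (treatment over
#' reference) across the supplied candidates — the pooled "x-fold more
#' antisense reads in the mutant" statistic. Restrict the input to
#' antisense-classified candidates for the antisense ratio.
#'
#' @param abundance Output of [quantify_candidates()] (optionally
#'   subsetted).
#' @param reference,treatment Genotype names (must match the `cpm_` columns
#'   present).
#' @return The ratio; `Inf` with a warning when the reference total is 0.
#' @export
global_antisense_ratio <- function(abundance, reference, treatment) {
  num <- sum(abundance[[paste0("cpm_", treatment)]])
  den <- sum(abundance[[paste0("cpm_", reference)]])
  if (den == 0) {
    warning("reference genotype has zero reads in the supplied candidates")
    return(Inf)
  }
  num / den
}

#' Candidates triggered in exactly one genotype
#'
#' @param candidates An `ncrna_candidates` data.frame.
#' @param genotype The genotype of interest.
#' @return The subset whose `trigger_genotypes` equals `{genotype}` — e.g.
#'   candidates exceeding the peak threshold only in the mutant.
#' @export
genotype_specific <- function(candidates, genotype) {
  all_g <- unique(unlist(strsplit(candidates$trigger_genotypes, ",")))
  if (nrow(candidates) && !genotype %in% all_g &&
      !genotype %in% candidates$end_source)
    stop("unknown genotype: ", genotype)
  sel <- vapply(strsplit(candidates$trigger_genotypes, ","),
                function(g) identical(g, genotype), logical(1))
  candidates[sel, , drop = FALSE]
}

#' Validation rate by coverage bin
#'
#' Bins candidate maximum coverage into left-closed right-open bins and
#' reports, per bin, the number of candidates and the fraction carrying a
#' positive validation label (validation labels are external inputs — e.g.
#' RT-PCR or gel-blot results — never inferred). Records below the first
#' edge land in an explicit below-threshold bin.
#'
#' @param max_coverage Numeric vector of per-candidate maximum depths.
#' @param validated Logical vector of validation labels.
#' @param bin_edges Increasing finite edges (default `c(50, 100, 150)`);
#'   the last bin is open-ended.
#' @return `data.frame` with `bin`, `n` and `fraction_validated`.
#' @export
detection_rate_bins <- function(max_coverage, validated,
                                bin_edges = c(50, 100, 150)) {
  stopifnot(length(max_coverage) == length(validated),
            !is.unsorted(bin_edges, strictly = TRUE))
  edges <- c(-Inf, bin_edges, Inf)
  labels <- c(paste0("<", bin_edges[1]),
              paste0("[", bin_edges[-length(bin_edges)], ",",
                     bin_edges[-1], ")"),
              paste0(">=", bin_edges[length(bin_edges)]))
  bin <- cut(max_coverage, breaks = edges, right = FALSE, labels = labels)
  n <- as.integer(table(bin))
  frac <- vapply(levels(bin), function(b) {
    sel <- bin == b
    if (!any(sel)) NA_real_ else mean(validated[sel])
  }, numeric(1))
  data.frame(bin = levels(bin), n = n, fraction_validated = unname(frac),
             stringsAsFactors = FALSE)
}
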