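#!/usr/bin/env Rscript
# Step 4 — genotype comparison by read-start binning.
#
# Quantifies each candidate's abundance (read starts, cpm), computes
# mutant/WT fold changes with a 0.5-cpm pseudocount, the pooled antisense
# ratio, and an in-silico detection-rate-by-coverage-bin table (labels =
# recovery of a planted unit, standing in for the wet-lab validation
# labels the tool would normally be given).

library(plastidnc)

ann <- load_annotation("results/sim/annotation.gff3")
covs <- lapply(c(WT = "WT", "pnp1-1" = "pnp1_1"), function(tag)
  coverage_from_placements(
    load_placements(file.path("results/sim",
                              paste0("placements_", tag, ".tsv"))),
    genome_length = 50000))
cand <- call_candidates(covs)
cls <- classify_candidates(cand, ann)
ab <- quantify_candidates(cand, covs, reference = "WT",
                          treatment = "pnp1-1", pseudocount = 0.5)
write.table(ab, "results/abundance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

anti <- ab[ab$candidate_id %in% cls$id[cls$ncrna_class == "antisense"], ]
ratio <- global_antisense_ratio(anti, "WT", "pnp1-1")
message(sprintf("pooled antisense pnp1-1/WT ratio: %.2f (over %d candidates)",
                ratio, nrow(anti)))
message(sprintf("median antisense per-candidate fold change: %.2f",
                median(anti$fold_change)))

# detection rate by coverage bin: label = candidate matches a planted unit
truth <- read.delim("results/sim/truth.bed", header = FALSE,
                    col.names = c("chrom", "start0", "end", "name",
                                  "score", "strand"))
planted <- data.frame(start = truth$start0 + 1L, stop = truth$end,
                      strand = truth$strand,
                      name = truth$name, class = sub(".*\\|", "", truth$name))
jac <- function(i, j)
  plastidnc:::interval_jaccard(cand$start[i], cand$stop[i],
                               planted$start[j], planted$stop[j])
label <- vapply(seq_len(nrow(cand)), function(i)
  any(vapply(seq_len(nrow(planted)), function(j)
    cand$strand[i] == planted$strand[j] && jac(i, j) >= 0.5,
    logical(1))), logical(1))
maxcov <- vapply(seq_len(nrow(cand)), function(i)
  max(vapply(cand$max_depth[[i]], identity, numeric(1))), numeric(1))
bins <- detection_rate_bins(maxcov, label)
write.table(bins, "results/detection_rate_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("detection rate by maximum-coverage bin:")
print(bins)
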