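#!/usr/bin/env Rscript
# Step 2 — call candidate ncRNA intervals from the simulated coverage.
#
# Applies the 50x trigger / 10x end rule per strand and genotype, unifies
# overlapping calls across genotypes with WT end precedence, and writes
# the candidate set (BED6 + invariant check) under results/.

library(plastidnc)

sim <- "results/sim"
covs <- lapply(c(WT = "WT", "pnp1-1" = "pnp1_1"), function(tag) {
  pl <- load_placements(file.path(sim, paste0("placements_", tag, ".tsv")))
  coverage_from_placements(pl, genome_length = 50000)
})

cfg <- caller_config() # 50x trigger, 10x ends, no merging
cand <- call_candidates(covs, cfg)
validate_candidates(cand, covs, cfg)
write_candidates_bed(cand, "results/candidates.bed")

message(sprintf("called %d candidates (span %d-%d nt, mean %.0f nt)",
                nrow(cand), min(interval_length(cand)),
                max(interval_length(cand)),
                mean(interval_length(cand))))
only_mut <- genotype_specific(cand, "pnp1-1")
message(sprintf("%d candidates exceed %dx only in pnp1-1",
                nrow(only_mut), cfg$peak_threshold))

# how much would gap-bridging change the picture? (the default keeps
# split peaks separate, as an RNA might be fragmented by structured ends)
for (gap in c(0, 25, 100))
  message(sprintf("merge_gap = %3d nt -> %d candidates", gap,
                  nrow(merge_adjacent(cand, gap))))
write.table(data.frame(id = cand$id, start = cand$start, stop = cand$stop,
                       strand = cand$strand, end_source = cand$end_source,
                       trigger_genotypes = cand$trigger_genotypes),
            "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/candidates.bed, results/candidates.tsv")
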