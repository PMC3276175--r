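#!/usr/bin/env Rscript
# Step 1 — simulate a toy plastome transcriptome for two genotypes.
#
# Builds the default 50 kb toy plastome (12 genes, 8 planted noncoding
# units), simulates 200,000 strand-specific 85-nt reads per genotype (WT
# and the ribonuclease mutant pnp1-1 with 4-fold antisense amplification
# and 3' extensions), and writes placements, per-strand bedGraph tracks
# and the ground truth under results/sim/.

library(plastidnc)

seed <- 7L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config()
toy <- build_toy_plastome(cfg, seed = seed)
write_annotation(toy$ann, file.path(out, "annotation.gff3"))
write_truth_bed(toy$truth, file.path(out, "truth.bed"))

exp_wt <- expected_unit_depth(toy$truth, cfg, "WT")
message("planted units and approximate expected WT depth:")
print(round(sort(exp_wt), 1))

for (g in names(cfg$genotype_effects)) {
  pl <- simulate_placements(toy$truth, cfg, g, seed = seed + match(
    g, names(cfg$genotype_effects)))
  tag <- gsub("[^A-Za-z0-9]", "_", g)
  write_placements(pl, file.path(out, paste0("placements_", tag, ".tsv")))
  cov <- coverage_from_placements(pl, cfg$genome_length)
  write_bedgraph_coverage(cov,
                          file.path(out, paste0(tag, "_plus.bedGraph")),
                          file.path(out, paste0(tag, "_minus.bedGraph")))
  message(sprintf("%s: %d placements; genome covered at >=1x: +%.1f%% -%.1f%%",
                  g, nrow(pl),
                  100 * covered_fraction(cov, "+"),
                  100 * covered_fraction(cov, "-")))
}
message("wrote ", out)
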