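#!/usr/bin/env Rscript
# Step 5 — scan candidates for small open reading frames.
#
# Noncoding candidates inevitably contain some ORFs; this reports, per
# candidate, the longest ATG-initiated ORF (>= 20 aa) on the candidate's
# own strand of the toy genome, with its peptide.

library(plastidnc)

cfg <- simulation_config()
toy <- build_toy_plastome(cfg, seed = 7L) # same genome as step 1
cand <- read.delim("results/candidates.tsv")

rows <- lapply(seq_len(nrow(cand)), function(i) {
  orf <- longest_orf_in_candidate(toy$genome, cand[i, ], min_aa = 20)
  if (is.null(orf)) return(NULL)
  seq <- substr(toy$genome$residues, cand$start[i], cand$stop[i])
  if (cand$strand[i] == "-")
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  data.frame(candidate = cand$id[i], strand = cand$strand[i],
             aa_length = orf$aa_length, frame = orf$frame,
             offset_start = orf$offset_start,
             peptide = orf_peptide(seq, orf))
})
orfs <- do.call(rbind, rows)
if (is.null(orfs)) {
  message("no candidate carries an ORF of >= 20 aa")
} else {
  write.table(orfs, "results/candidate_orfs.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%d of %d candidates carry an ORF >= 20 aa (longest %d aa)",
                  nrow(orfs), nrow(cand), max(orfs$aa_length)))
}
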