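## Benchmark scenario configurations shared by the test-suite, the
## acceptance script and the analysis scripts. Parameters are fixed design
## choices (documented in the methods vignette), not tuning knobs.

#' Recovery benchmark: 20 planted antisense units on a 50 kb toy plastome
#'
#' Ten 1200-nt sense genes, each with two antisense units (400 and 300 nt)
#' planted opposite its body, separated by 300 nt. Unit copy numbers and
#' the 50,000-read sample size put the expected mid-unit depth near 100x
#' (comfortably above the 60x floor the benchmark assumes) with sense genes
#' near 300x. One genotype (WT). `prob_structured_end` defaults to 0 so
#' that peaks are clean; set it to 0.5 to reproduce the split-peak
#' fragmentation artifact.
#'
#' @param prob_structured_end Structured-end probability (default 0).
#' @return A [simulation_config()].
#' @export
recovery_scenario_config <- function(prob_structured_end = 0) {
  gstart <- seq(2000, by = 4500, length.out = 10)
  genes <- data.frame(
    name = sprintf("gene%02d", 1:10),
    start = gstart, stop = gstart + 1199, strand = "+",
    kind = "protein", cluster_id = NA_character_,
    stringsAsFactors = FALSE)
  units <- data.frame(
    name = c(sprintf("as-%s-a", genes$name), sprintf("as-%s-b", genes$name)),
    start = c(gstart + 150, gstart + 850),
    stop = c(gstart + 549, gstart + 1149),
    strand = "-", mean_copies = 40, has_own_promoter = TRUE,
    stringsAsFactors = FALSE)
  simulation_config(
    genome_length = 50000, gene_layout = genes,
    sense_expression = setNames(rep(120, 10), genes$name),
    antisense_units = units[order(units$start), ],
    genotype_effects = list(WT = list(antisense_amplification = 1,
                                      three_prime_extension = 0)),
    end_suppression = list(prob_structured_end = prob_structured_end,
                           suppressed_span = 40),
    depth_target = 50000)
}

#' Fold-change benchmark: 4-fold antisense amplification in the mutant
#'
#' Same gene backbone as [recovery_scenario_config()] but with large
#' molecule counts (1200 sense / 30 antisense copies, keeping the antisense
#' share of the fragment pool near 2.5%, as befits a minority antisense
#' population) so that transcript-copy Poisson noise is small relative to
#' the amplification being estimated, and 200,000 reads per genotype. The
#' mutant's 3' extension is disabled here: the benchmark isolates the
#' pooled amplification ratio, and extensions would shift mutant read
#' starts out of the WT-defined candidate spans, confounding the
#' read-start-binning denominator (they are exercised by the default and
#' mutant-only configurations instead).
#'
#' @param antisense_amplification Mutant/WT antisense copy ratio
#'   (default 4).
#' @param antisense_copies Mean WT copies per antisense unit (default 30).
#' @return A [simulation_config()].
#' @export
foldchange_scenario_config <- function(antisense_amplification = 4,
                                       antisense_copies = 30) {
  base <- recovery_scenario_config()
  units <- base$antisense_units
  units$mean_copies <- antisense_copies
  simulation_config(
    genome_length = base$genome_length, gene_layout = base$gene_layout,
    sense_expression = setNames(rep(1200, 10), base$gene_layout$name),
    antisense_units = units,
    genotype_effects = list(
      WT = list(antisense_amplification = 1, three_prime_extension = 0),
      "pnp1-1" = list(antisense_amplification = antisense_amplification,
                      three_prime_extension = 0)),
    end_suppression = list(prob_structured_end = 0, suppressed_span = 40),
    depth_target = 200000)
}

#' Mutant-only benchmark: one unit below threshold in WT, above in mutant
#'
#' A single antisense unit whose expected depth is ~30x in WT (under the
#' 50x trigger) and ~80x in the mutant (amplification 80/30), so the
#' candidate must be reported as triggered in the mutant only. Depth here
#' means what the caller sees — the track's peak. Copy numbers are large
#' (3600 sense / 180 antisense molecules, calibrated so the WT track peaks
#' near 30x at 50,000 reads) keeping per-base depth near its Poisson limit
#' and the WT track reliably below the 50x trigger.
#'
#' @return A [simulation_config()].
#' @export
mutant_only_scenario_config <- function() {
  base <- recovery_scenario_config()
  units <- data.frame(name = "as-gene05-only", start = 20150, stop = 20549,
                      strand = "-", mean_copies = 180,
                      has_own_promoter = TRUE, stringsAsFactors = FALSE)
  simulation_config(
    genome_length = base$genome_length, gene_layout = base$gene_layout,
    sense_expression = setNames(rep(3600, 10), base$gene_layout$name),
    antisense_units = units,
    genotype_effects = list(
      WT = list(antisense_amplification = 1, three_prime_extension = 0),
      "pnp1-1" = list(antisense_amplification = 80 / 30,
                      three_prime_extension = 0)),
    end_suppression = list(prob_structured_end = 0, suppressed_span = 40),
    depth_target = 50000)
}
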