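---
title: "Threshold-based discovery of plastid noncoding RNAs: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based discovery of plastid noncoding RNAs: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidnc)
```

## The procedure and its assumptions

`plastidnc` detects noncoding RNA (ncRNA) candidates in a plastid
transcriptome from strand-specific coverage alone. The operational unit is
the *transcription peak*: a maximal run of consecutive bases whose depth
stays at or above an end threshold (10x) and which contains at least one
base at or above a trigger threshold (50x). The procedure assumes

* a directional library, so a read's alignment strand is the transcript
  strand (no strand inference from splice motifs);
* near-complete transcription of both genome strands, so candidate calling
  must be threshold-based rather than presence/absence;
* that transcript termini are under-represented: the library chemistry
  ligates adapters to RNA ends, and ends engaged in secondary structure
  ligate poorly, which both truncates called intervals and can split one
  transcript into several peaks. The caller therefore reports *intervals of
  well-supported transcription*, not transcript models, and merging across
  gaps (`merge_gap`) is off by default.

Two genotypes are analysed jointly (a wild type and a ribonuclease mutant
whose loss amplifies antisense RNA). Overlapping peaks from different
genotypes are unified; the unified interval's termini come from the
highest-priority genotype that triggered — wild-type precedence, so
mutant-only candidates keep mutant-defined ends. Candidates are then
classified against the annotation: *antisense* when they overlap any
opposite-strand gene or intron; otherwise *intergenic* when they fall
within a transcription cluster's span without same-strand gene overlap;
otherwise rejected as putative fragments of known sense transcripts (the
pipeline deliberately does not call such fragments ncRNAs).

## Thresholds and conventions

| parameter | default | meaning |
|---|---|---|
| `peak_threshold` | 50x | trigger depth; *inclusive* (`>= 50`), reading "a minimum of 50x" literally |
| `end_threshold` | 10x | a base at 10x still belongs to the run; the first base at 9x ends it |
| `merge_gap` | 0 nt | gap-bridging between same-strand candidates; off because split peaks are data |
| `window_5p`, `window_3p` | 25 nt | pairing-region windows around a target's termini |
| pseudocount | 0.5 cpm | keeps mutant-only fold changes finite |

Coordinates are 1-based inclusive (GenBank convention); BED/bedGraph
exports convert to 0-based half-open at the boundary. Candidate *length*
is reported as the endpoint difference `stop - start`: on the packaged
107-candidate catalog this convention reproduces both the published
minimum (48 nt) and the published mean (217 nt), so the apparent conflict
between the two length conventions dissolves — the inclusive span
`stop - start + 1` is exposed as `interval_span()`. Genomes are treated as
linear within `[1, length]`; features and queries wrapping the circular
origin are rejected (no catalog interval wraps).

Doubly-placed reads — the aligner accepts up to two placements so reads
from the large inverted repeat map to both copies — contribute full weight
at both placements by default, keeping the repeat copies symmetric; a
`multi_weight = 0.5` option halves them. Whether the original read-start
binning counted such reads once or twice is not documented; full weight is
the package's documented default.

Several choices the source material leaves open are decided here and
documented rather than inferred: the 5'/3' pairing windows (25 nt, a small
window around the translation-initiation region and terminus); dual-class
candidates (antisense overlap beats intergenic); the principal target for
naming (largest overlap, ties to the smaller start, except that a
candidate wholly inside an opposite-strand intron is named after the
intron, since an intron can never win on raw overlap against the gene
containing it); and ASCII `-5p`/`-3p` name suffixes for single-terminus
candidates. rRNA-antisense candidates are not filtered — their scarcity is
an observed outcome, not a rule — though an rRNA mask can be applied by
editing the annotation.

## Quantification

Abundance per candidate and genotype is the number of read *starts* inside
the candidate interval on its strand, normalised to counts per million
placements (cpm). The genotype comparison statistic is pooled: the ratio
of summed cpm across candidates (treatment over reference), matching the
notion of "x-fold more sequencing reads" as a statement about totals
rather than a mean of per-candidate ratios. Per-candidate fold changes use
a 0.5-cpm pseudocount. Note an inherent property of a fixed sequencing
budget: if antisense mass is amplified `a`-fold while the library size is
constant, the measurable pooled cpm ratio is `a (S + A) / (S + aA)` for
sense mass `S` and antisense mass `A`, slightly below `a`; with antisense
at a few percent of the pool (as in these libraries) the attenuation is
small. No dispersion model is fitted — the source procedure computes none
— so these are descriptive statistics, not differential-expression tests.

## The simulator

`simulation_config()` describes the emulated study conditions: a 50 kb
toy plastome; 85-nt reads; fragments below 80 nt lost (the library retains
transcripts above ~80 nt); 30% of sense molecules reading through their
terminator with a geometric extension (mean 200 nt — transcription
termination in plastids is inefficient); antisense units with dedicated
promoters; a mutant genotype with 4-fold antisense amplification and
60-nt-mean 3' extensions; and structured (ligation-resistant) ends.

Molecules are drawn Poisson per transcription unit. Each molecule's
termini receive +-10 nt uniform microheterogeneity (`terminus_jitter`):
plastid transcripts genuinely show multiple 5'/3' ends, and without the
jitter all molecules of a unit share exact termini, so identical reads
stack there and the peak depth runs well above the mean — an artifact of
over-rigid simulation rather than of the method. Molecules are fragmented
by uniform breakpoints (mean fragment 150 nt) with short pieces merged
leftward and sub-80-nt pieces lost; reads of 85 nt are sampled uniformly
within fragments, on the molecule's strand, to a fixed total per genotype.

End suppression has two components, both governed by
`prob_structured_end` (default 0.3) and `suppressed_span` (40 nt):

1. *terminal trimming* — each molecule terminus is unsequenceable over the
   suppressed span with that probability, thinning coverage at transcript
   ends;
2. *structured sites* — fixed positions drawn once per unit at truth-build
   time (one candidate site per 200-nt tile, present with that
   probability); every molecule is cleaved there and the surrounding span
   is unsequenceable.

The second component is what reproduces the observed splitting of single
transcripts into multiple coverage peaks: suppression applied only at
molecule termini can narrow a peak but never split it, because interior
coverage is unaffected. A structured site, by contrast, is a property of
the RNA sequence shared by all molecules of the unit, so it carves a
reproducible gap into the coverage — exactly the fragmentation artifact
the caller must cope with. Recovery is scored by strand-aware interval
Jaccard (default 0.5), with `fragmentation_ratio` = candidates overlapping
truth / recovered units.

What the simulator does **not** model: sequence-dependent ligation bias
(structured sites are random, not folded), base-calling errors and quality,
PCR duplicates, spliced alignment, and the inverted repeat's duplicated
gene content (multi-placement weighting is exercised on constructed
fixtures instead). Passing recovery benchmarks therefore demonstrates the
pipeline's correctness on data with the *shape* of the real phenomenon —
read-through, antisense amplification, end bias, split peaks — not
performance on any particular real library.

## Benchmark scenarios and problem sizes

Three fixed scenario configurations (in `R/scenarios.R`) are shared by the
tests, the acceptance script and the analysis scripts; their parameters
are design choices made once:

* **Recovery** — ten 1200-nt sense genes on a 50 kb plastome, two
  antisense units (400/300 nt) opposite each gene body, 50,000 reads, one
  genotype; copy numbers put the expected mid-unit depth near 100x
  (sense ~300x), comfortably above the 60x floor the benchmark assumes.
  With structured ends off, all 30 planted units are recovered at Jaccard
  >= 0.5 with precision 1; with `prob_structured_end = 0.5`, most units
  carry at least one interior site, and the fragmentation ratio exceeds 1
  in essentially all of 100 replicates.
* **Fold change** — the same backbone with 1200/30 sense/antisense copies
  (antisense ~2.5% of the fragment pool, a minority population) and
  200,000 reads per genotype. Large molecule counts keep copy-number
  Poisson noise small relative to the 4-fold amplification being
  estimated. The mutant 3' extension is disabled *in this scenario only*:
  extensions shift mutant read starts out of the WT-defined candidate
  spans and would confound the read-start-binning denominator with an
  unrelated phenotype (it is exercised by the default and mutant-only
  configurations). The expected pooled ratio is ~3.7 after the
  fixed-budget attenuation above; the acceptance band (3.2-4.8) brackets
  it.
* **Mutant-only** — one 400-nt antisense unit calibrated so the WT track
  *peaks* near 30x (clearly under the 50x trigger) while the mutant peaks
  near 80x; sense copies are large (3600) so depth is near its Poisson
  limit. Calibration was empirical: the analytic fragment-pool model
  underestimates realised depth by ~1.3x because minimum-fragment merging
  shrinks long genes' fragment counts disproportionately.

Problem sizes throughout (50 kb genomes, 50-200k reads, 100 replicates,
1,000 oracle tracks, 500 oracle sequences) are chosen so the full test
suite and the acceptance script each run in a few minutes on one CPU while
leaving the stochastic assertions wide margins.

## Numerical and degenerate-input conventions

* Empty depth tracks, empty placement sets and `depth_target = 0` yield
  empty (not failing) results; rejections in classification are data, not
  errors.
* `evaluate_recovery` with no candidates reports precision 1 flagged
  `no_candidates`, and a fragmentation ratio of `NA` when nothing is
  recovered.
* bedGraph-derived coverage has no read-start tracks; operations that need
  them (`read_start_count`, quantification) refuse with an explicit error
  rather than fabricating starts from depth.
* A zero reference total in the pooled ratio returns `Inf` with a warning.
* Ties for the longest ORF go to the smallest offset; start codons are ATG
  only by default (configurable), and codons containing `N` never match
  start or stop.
* The catalog's one qualitative gel-blot entry (a smear) parses as a
  detection with `NA` size. Counting the catalog's blot detections gives
  49, one more than its own prose summary states; the table is taken as
  authoritative and the discrepancy is surfaced rather than patched.

## Known limitations

The caller is purely threshold-based: no replicate awareness, no FDR
control, no probabilistic segmentation — fidelity to the original
procedure is the point. Wrap-around (origin-crossing) features are
unsupported. Cluster membership (`cluster_id`) is user-supplied; no
operon inference is attempted. ORF homology search (e.g. against other
plastomes) is out of scope. The validation labels consumed by
`detection_rate_bins()` are always external inputs: the package never
infers wet-lab outcomes.
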