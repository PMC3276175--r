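## Toy plastome transcriptome simulator with planted ground truth.
##
## Emulates the transcriptional phenomena of the chloroplast: sense
## transcription with inefficient termination (3' read-through), antisense
## units with dedicated promoters, a ribonuclease-mutant genotype with
## global antisense amplification and 3' extensions, short-fragment loss
## (the library retains fragments above ~80 nt), 85-nt reads, and
## ligation-resistant structured ends that suppress coverage and split one
## transcript into several peaks.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a 50 kb circular toy
#' plastome, 85-nt reads, fragments below 80 nt lost, 30% read-through past
#' sense terminators, a mutant genotype with 4-fold antisense amplification
#' and a 60-nt mean 3' extension, and 30% structured (ligation-resistant)
#' ends suppressing 40-nt spans.
#'
#' @param genome_length Genome length in nt (default 50000).
#' @param gene_layout `data.frame(name, start, stop, strand, kind,
#'   cluster_id)` of sense genes; defaults to [toy_gene_layout()]. Same-
#'   strand genes may not overlap.
#' @param sense_expression Named numeric vector, gene -> mean transcript
#'   copies (defaults: 120 per protein/rRNA gene, 300 per tRNA).
#' @param read_through_prob Probability a sense transcript continues past
#'   its terminator (default 0.3).
#' @param read_through_mean Mean length (nt) of the geometric read-through
#'   extension (default 200).
#' @param antisense_units `data.frame(name, start, stop, strand,
#'   mean_copies, has_own_promoter)`; defaults to [toy_antisense_units()].
#' @param genotype_effects Named list per genotype with elements
#'   `antisense_amplification` and `three_prime_extension` (nt mean);
#'   default `WT` (1, 0) and `pnp1-1` (4, 60).
#' @param read_length Read length in nt (default 85).
#' @param min_fragment Fragments shorter than this are lost (default 80).
#' @param fragment_mean Mean hydrolysis fragment length in nt (default 150).
#' @param terminus_jitter Half-width (nt) of the uniform per-molecule
#'   terminus microheterogeneity (default 10), emulating the 5'/3' end
#'   heterogeneity of chloroplast transcripts; without it, all molecules
#'   of a unit share exact termini and identical reads stack there.
#' @param end_suppression List with `prob_structured_end` (default 0.3) and
#'   `suppressed_span` (nt, default 40).
#' @param depth_target Total reads per genotype sample (default 200000).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(genome_length = 50000,
                              gene_layout = toy_gene_layout(),
                              sense_expression = NULL,
                              read_through_prob = 0.3,
                              read_through_mean = 200,
                              antisense_units = toy_antisense_units(),
                              genotype_effects = list(
                                "WT" = list(antisense_amplification = 1,
                                            three_prime_extension = 0),
                                "pnp1-1" = list(antisense_amplification = 4,
                                                three_prime_extension = 60)),
                              read_length = 85,
                              min_fragment = 80,
                              fragment_mean = 150,
                              terminus_jitter = 10,
                              end_suppression = list(
                                prob_structured_end = 0.3,
                                suppressed_span = 40),
                              depth_target = 200000) {
  stopifnot(read_through_prob >= 0, read_through_prob <= 1,
            terminus_jitter >= 0,
            end_suppression$prob_structured_end >= 0,
            end_suppression$prob_structured_end <= 1,
            end_suppression$suppressed_span >= 0,
            read_length >= 1, min_fragment >= 1, fragment_mean >= 1,
            depth_target >= 0)
  gl <- gene_layout
  stopifnot(all(gl$start <= gl$stop), all(gl$start >= 1),
            all(gl$stop <= genome_length))
  for (s in c("+", "-")) {
    g <- gl[gl$strand == s, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1L && any(g$start[-1] <= g$stop[-nrow(g)]))
      stop("overlapping same-strand genes in gene_layout")
  }
  if (is.null(sense_expression)) {
    sense_expression <- setNames(
      ifelse(gl$kind == "tRNA", 300, 120), gl$name)
  }
  miss <- setdiff(gl$name, names(sense_expression))
  if (length(miss)) stop("sense_expression missing genes: ",
                         paste(miss, collapse = ", "))
  au <- antisense_units
  if (nrow(au)) {
    stopifnot(all(au$start <= au$stop), all(au$start >= 1),
              all(au$stop <= genome_length),
              all(au$strand %in% c("+", "-")))
    if (is.null(au$name)) au$name <- sprintf("unit%02d", seq_len(nrow(au)))
    if (is.null(au$has_own_promoter)) au$has_own_promoter <- TRUE
  }
  structure(list(genome_length = as.integer(genome_length),
                 gene_layout = gl, sense_expression = sense_expression,
                 read_through_prob = read_through_prob,
                 read_through_mean = read_through_mean,
                 antisense_units = au,
                 genotype_effects = genotype_effects,
                 read_length = as.integer(read_length),
                 min_fragment = as.integer(min_fragment),
                 fragment_mean = fragment_mean,
                 terminus_jitter = as.integer(terminus_jitter),
                 end_suppression = end_suppression,
                 depth_target = as.integer(depth_target)),
            class = "sim_config")
}

#' Default toy plastome gene layout
#'
#' Twelve well-separated genes on a 50 kb toy plastome, including a tRNA,
#' an rRNA and one two-gene transcription cluster (`psb_op`) whose internal
#' gap hosts an intergenic ncRNA in [toy_antisense_units()].
#'
#' @return A `data.frame` usable as `gene_layout` in [simulation_config()].
#' @export
toy_gene_layout <- function() {
  data.frame(
    name = c("psbA", "trnK", "rbcL", "atpB", "psbB", "psbH", "ndhF",
             "rrn16", "ycf2", "rpoB", "psaA", "ndhD"),
    start = c(2000, 4500, 7000, 11000, 15000, 16600, 20000, 24000, 28000,
              33000, 37000, 44000),
    stop = c(3200, 4585, 8400, 12200, 16200, 17000, 21200, 25400, 29800,
             34400, 38200, 45200),
    strand = c("+", "+", "+", "-", "+", "+", "-", "+", "+", "-", "+", "-"),
    kind = c("protein", "tRNA", "protein", "protein", "protein", "protein",
             "protein", "rRNA", "protein", "protein", "protein", "protein"),
    cluster_id = c(NA, NA, NA, NA, "psb_op", "psb_op", NA, NA, NA, NA,
                   NA, NA),
    stringsAsFactors = FALSE)
}

#' Default planted antisense / intergenic units
#'
#' Eight noncoding units matching [toy_gene_layout()]: seven antisense to
#' gene bodies or termini and one intergenic unit inside the `psb_op`
#' cluster gap (a read-through product, no dedicated promoter).
#'
#' @return A `data.frame` usable as `antisense_units` in
#'   [simulation_config()].
#' @export
toy_antisense_units <- function() {
  data.frame(
    name = c("as-psbA", "as-rbcL", "as-atpB", "nc-psbB-psbHint", "as-ndhF",
             "as-ycf2", "as-psaA-5p", "as-ndhD"),
    start = c(2300, 7400, 11300, 16250, 20300, 28400, 36950, 44300),
    stop = c(2700, 7800, 11700, 16550, 20700, 28800, 37200, 44700),
    strand = c("-", "-", "+", "-", "+", "-", "-", "+"),
    mean_copies = 40,
    has_own_promoter = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Build a toy plastome with planted ground truth
#'
#' Deterministic for a fixed seed: random residues, annotation from the
#' gene layout, and a ground-truth table holding every transcribed unit
#' (sense genes plus noncoding units) with genotype-wise expected copies
#' and, when end suppression is active, the positions of structured
#' (ligation-resistant) sites — one candidate site per 200-nt tile of each
#' unit, present with probability `prob_structured_end`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return List with elements `genome` ([plastome()]), `ann`
#'   ([annotation()]) and `truth` (a `ground_truth` data.frame with columns
#'   `name`, `start`, `stop`, `strand`, `class`
#'   (sense/antisense/intergenic), `has_own_promoter`, list-columns
#'   `copies` (named per genotype) and `sites`).
#' @export
build_toy_plastome <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  residues <- paste(sample(c("A", "C", "G", "T"), cfg$genome_length,
                           replace = TRUE, prob = c(.32, .18, .18, .32)),
                    collapse = "")
  genome <- plastome(cfg$genome_length, residues, circular = TRUE)
  ann <- annotation(cfg$gene_layout, cfg$genome_length)
  gl <- cfg$gene_layout
  genos <- names(cfg$genotype_effects)
  units <- rbind(
    data.frame(name = gl$name, start = gl$start, stop = gl$stop,
               strand = gl$strand, class = "sense",
               has_own_promoter = TRUE, mean_copies =
                 unname(cfg$sense_expression[gl$name]),
               stringsAsFactors = FALSE),
    if (nrow(cfg$antisense_units)) data.frame(
      name = cfg$antisense_units$name,
      start = cfg$antisense_units$start,
      stop = cfg$antisense_units$stop,
      strand = cfg$antisense_units$strand,
      class = NA_character_,
      has_own_promoter = cfg$antisense_units$has_own_promoter,
      mean_copies = cfg$antisense_units$mean_copies,
      stringsAsFactors = FALSE))
  for (i in which(is.na(units$class))) {
    opp <- features_overlapping(ann, units$start[i], units$stop[i],
                                paste0("opposite-of:", units$strand[i]))
    units$class[i] <- if (nrow(opp)) "antisense" else "intergenic"
  }
  units$copies <- lapply(seq_len(nrow(units)), function(i) {
    vapply(genos, function(g) {
      amp <- if (units$class[i] == "sense") 1 else
        cfg$genotype_effects[[g]]$antisense_amplification
      units$mean_copies[i] * amp
    }, numeric(1))
  })
  p <- cfg$end_suppression$prob_structured_end
  units$sites <- lapply(seq_len(nrow(units)), function(i) {
    if (p <= 0) return(integer())
    len <- units$stop[i] - units$start[i] + 1L
    tiles <- seq(units$start[i], units$stop[i], by = 200L)
    hit <- runif(length(tiles)) < p
    if (!any(hit)) return(integer())
    as.integer(tiles[hit] +
                 floor(runif(sum(hit)) * pmin(200L, units$stop[i] -
                                                tiles[hit] + 1L)))
  })
  class(units) <- c("ground_truth", "data.frame")
  list(genome = genome, ann = ann, truth = units)
}

# cut [s, e] by removing windows, keeping pieces >= min_len
cut_intervals <- function(s, e, windows, min_len) {
  pieces <- matrix(c(s, e), ncol = 2)
  if (nrow(windows)) for (k in seq_len(nrow(windows))) {
    out <- list()
    for (j in seq_len(nrow(pieces))) {
      ps <- pieces[j, 1]; pe <- pieces[j, 2]
      ws <- windows[k, 1]; we <- windows[k, 2]
      if (we < ps || ws > pe) { out[[length(out) + 1L]] <- c(ps, pe); next }
      if (ws > ps) out[[length(out) + 1L]] <- c(ps, ws - 1L)
      if (we < pe) out[[length(out) + 1L]] <- c(we + 1L, pe)
    }
    pieces <- do.call(rbind, out)
    if (is.null(pieces)) return(matrix(numeric(0), ncol = 2))
  }
  pieces[pieces[, 2] - pieces[, 1] + 1 >= min_len, , drop = FALSE]
}

# uniform-breakpoint fragmentation with a minimum-length floor: short
# pieces are merged into their left neighbour
fragment_piece <- function(s, e, fragment_mean, min_fragment) {
  len <- e - s + 1
  if (len < min_fragment) return(NULL)
  k <- rpois(1, max(0, len / fragment_mean - 1))
  if (k == 0) return(matrix(c(s, e), ncol = 2))
  cuts <- sort(s - 1 + ceiling(runif(k) * (len - 1)))
  bounds <- c(s - 1, cuts, e)
  starts <- bounds[-length(bounds)] + 1
  stops <- bounds[-1]
  keep_s <- starts[1]; out <- NULL
  for (j in seq_along(starts)) {
    if (stops[j] - keep_s + 1 >= min_fragment) {
      out <- rbind(out, c(keep_s, stops[j]))
      if (j < length(starts)) keep_s <- starts[j + 1]
    }
  }
  out
}

#' Simulate strand-specific read placements for one genotype
#'
#' Transcript molecules are drawn Poisson per unit (antisense copies scaled
#' by the genotype's amplification); sense molecules read through their
#' terminator with `read_through_prob` (geometric extension); mutant
#' molecules of noncoding units gain geometric 3' extensions; molecules are
#' cleaved at their unit's structured sites, whose `suppressed_span`
#' surroundings are unsequenceable, and molecule termini are trimmed by
#' `suppressed_span` with `prob_structured_end`; pieces are fragmented with
#' uniform breakpoints (mean `fragment_mean`), fragments under
#' `min_fragment` are lost, and `depth_target` reads of `read_length` are
#' sampled uniformly within fragments, on the molecule's strand.
#'
#' @param truth `ground_truth` from [build_toy_plastome()].
#' @param cfg The same [simulation_config()].
#' @param genotype Genotype name present in `cfg$genotype_effects`.
#' @param seed Integer seed; fixed seed gives bit-identical placements.
#' @return A placement `data.frame` as from [placements()].
#' @export
simulate_placements <- function(truth, cfg, genotype, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!genotype %in% names(cfg$genotype_effects))
    stop("unknown genotype: ", genotype)
  set.seed(seed)
  if (cfg$depth_target == 0)
    return(placements(character(), integer(), integer(), character()))
  eff <- cfg$genotype_effects[[genotype]]
  p_end <- cfg$end_suppression$prob_structured_end
  span <- cfg$end_suppression$suppressed_span
  glen <- cfg$genome_length
  frag_s <- frag_e <- frag_str <- list()
  for (i in seq_len(nrow(truth))) {
    n_mol <- rpois(1, truth$copies[[i]][[genotype]])
    if (n_mol == 0) next
    s <- rep(truth$start[i], n_mol); e <- rep(truth$stop[i], n_mol)
    strand <- truth$strand[i]
    if (cfg$terminus_jitter > 0) {
      j <- cfg$terminus_jitter
      s <- pmax(1, s + sample.int(2L * j + 1L, n_mol, replace = TRUE) -
                  j - 1L)
      e <- pmin(glen, e + sample.int(2L * j + 1L, n_mol, replace = TRUE) -
                  j - 1L)
    }
    ext <- numeric(n_mol)
    if (truth$class[i] == "sense" && cfg$read_through_prob > 0) {
      thru <- runif(n_mol) < cfg$read_through_prob
      ext[thru] <- rgeom(sum(thru), 1 / (1 + cfg$read_through_mean))
    } else if (truth$class[i] != "sense" &&
               eff$three_prime_extension > 0) {
      ext <- rgeom(n_mol, 1 / (1 + eff$three_prime_extension))
    }
    if (strand == "+") e <- pmin(glen, e + ext) else s <- pmax(1, s - ext)
    if (p_end > 0 && span > 0) {
      s <- s + span * (runif(n_mol) < p_end)
      e <- e - span * (runif(n_mol) < p_end)
    }
    sites <- truth$sites[[i]]
    windows <- if (length(sites))
      cbind(sites - span %/% 2L, sites + span %/% 2L) else
        matrix(numeric(0), ncol = 2)
    for (m in seq_len(n_mol)) {
      if (e[m] - s[m] + 1 < cfg$min_fragment) next
      pieces <- cut_intervals(s[m], e[m], windows, cfg$min_fragment)
      for (j in seq_len(nrow(pieces))) {
        fr <- fragment_piece(pieces[j, 1], pieces[j, 2],
                             cfg$fragment_mean, cfg$min_fragment)
        if (!is.null(fr)) {
          frag_s[[length(frag_s) + 1L]] <- fr[, 1]
          frag_e[[length(frag_e) + 1L]] <- fr[, 2]
          frag_str[[length(frag_str) + 1L]] <- rep(strand, nrow(fr))
        }
      }
    }
  }
  fs <- unlist(frag_s); fe <- unlist(frag_e); fstr <- unlist(frag_str)
  if (is.null(fs) || !length(fs))
    return(placements(character(), integer(), integer(), character()))
  idx <- sample.int(length(fs), cfg$depth_target, replace = TRUE)
  flen <- fe[idx] - fs[idx] + 1
  rl <- pmin(cfg$read_length, flen)
  offset <- floor(runif(cfg$depth_target) * (flen - rl + 1))
  rs <- fs[idx] + offset
  re <- rs + rl - 1
  placements(sprintf("r%07d", seq_len(cfg$depth_target)),
             rs, re, fstr[idx])
}

#' Approximate expected coverage depth per unit
#'
#' Deterministic design-time estimate: reads land on a unit in proportion
#' to its share of the fragment pool (copies times expected fragments per
#' molecule), and depth is reads times read length over unit length.
#' Ignores end suppression, extensions and edge effects.
#'
#' @param truth `ground_truth` from [build_toy_plastome()].
#' @param cfg The [simulation_config()].
#' @param genotype Genotype name.
#' @return Named numeric vector of expected mid-unit depths.
#' @export
expected_unit_depth <- function(truth, cfg, genotype) {
  len <- truth$stop - truth$start + 1
  copies <- vapply(truth$copies, `[[`, numeric(1), genotype)
  frags <- copies * pmax(1, len / cfg$fragment_mean)
  reads <- cfg$depth_target * frags / sum(frags)
  setNames(reads * cfg$read_length / len, truth$name)
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  inter / (max(e1, e2) - min(s1, s2) + 1)
}

#' Score candidate recovery against planted truth
#'
#' A planted unit is recovered when at least one same-strand candidate
#' matches it at Jaccard >= `min_jaccard`. Precision is the fraction of
#' candidates matching some unit; with no candidates it is reported as 1
#' with attribute `no_candidates`. The fragmentation ratio — candidates
#' overlapping truth divided by recovered units — exceeds 1 when single
#' transcripts are split into several peaks; it is `NA` when nothing is
#' recovered.
#'
#' @param candidates An `ncrna_candidates` data.frame.
#' @param truth `ground_truth` (optionally subset to the classes of
#'   interest).
#' @param min_jaccard Matching threshold (default 0.5).
#' @return List with `precision`, `recall`, `fragmentation_ratio`,
#'   `n_candidates`, `n_units`, `n_recovered`.
#' @export
evaluate_recovery <- function(candidates, truth, min_jaccard = 0.5) {
  n_c <- nrow(candidates); n_u <- nrow(truth)
  jac <- matrix(0, n_c, n_u)
  for (i in seq_len(n_c)) for (j in seq_len(n_u)) {
    if (candidates$strand[i] == truth$strand[j])
      jac[i, j] <- interval_jaccard(candidates$start[i], candidates$stop[i],
                                    truth$start[j], truth$stop[j])
  }
  matched_c <- if (n_c) apply(jac >= min_jaccard, 1, any) else logical()
  recovered_u <- if (n_u && n_c) apply(jac >= min_jaccard, 2, any) else
    logical(n_u)
  overlapping_c <- if (n_c) apply(jac > 0, 1, any) else logical()
  precision <- if (n_c == 0) structure(1, no_candidates = TRUE) else
    mean(matched_c)
  n_rec <- sum(recovered_u)
  list(precision = precision,
       recall = if (n_u) n_rec / n_u else NA_real_,
       fragmentation_ratio = if (n_rec) sum(overlapping_c) / n_rec
         else NA_real_,
       n_candidates = n_c, n_units = n_u, n_recovered = n_rec)
}

#' Write ground truth as BED6
#'
#' @param truth `ground_truth` data.frame.
#' @param path Output file; the name field carries `unit|class`.
#' @param seqname Chromosome name.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path, seqname = "plastome") {
  bed <- data.frame(chrom = seqname, start = truth$start - 1L,
                    end = truth$stop,
                    name = paste0(truth$name, "|", truth$class),
                    score = 0, strand = truth$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
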