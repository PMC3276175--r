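## Orchestration: coverage -> call -> classify -> quantify -> report.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Values are returned as character; callers coerce.
#'
#' @param path Config file.
#' @return Named character vector.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  setNames(trimws(vapply(m, `[`, character(1), 3)),
           trimws(vapply(m, `[`, character(1), 2)))
}

#' Run the discovery pipeline end to end
#'
#' Builds stranded coverage per genotype, calls candidates with wild-type
#' end precedence, classifies them against the annotation, quantifies
#' read-start abundance and fold changes, and (optionally) writes BED /
#' GFF3 / TSV outputs plus a text summary.
#'
#' @param genotypes Named list: per genotype either a placement
#'   `data.frame`, a path to a placement table / SAM / BAM, or a
#'   `stranded_coverage`. Order sets end precedence (first = wild type).
#' @param ann A `plastid_annotation` (or a GFF3 path).
#' @param genome_length Genome length; defaults to `ann$genome_length`.
#' @param cfg A [caller_config()].
#' @param window_5p,window_3p Pairing windows for [classify_candidates()].
#' @param pseudocount Fold-change pseudocount in cpm (default 0.5).
#' @param out_dir Output directory; `NULL` (default) writes nothing.
#' @return Invisibly, a report bundle: `candidates`, `classified`,
#'   `abundance`, `summary` (a list with candidate counts, class split,
#'   size stats, genotype-specific counts and the pooled antisense ratio
#'   when two or more genotypes are supplied).
#' @export
run_pipeline <- function(genotypes, ann, genome_length = NULL,
                         cfg = caller_config(), window_5p = 25,
                         window_3p = 25, pseudocount = 0.5,
                         out_dir = NULL) {
  if (is.character(ann)) ann <- load_annotation(ann)
  stopifnot(inherits(ann, "plastid_annotation"))
  if (is.null(genome_length)) genome_length <- ann$genome_length
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop("genotypes must be a named list")
  coverage <- lapply(genotypes, function(x) {
    if (inherits(x, "stranded_coverage")) return(x)
    if (is.character(x)) {
      if (!file.exists(x)) stop("missing input file: ", x)
      x <- load_placements(x)
    }
    coverage_from_placements(x, genome_length)
  })
  candidates <- call_candidates(coverage, cfg)
  classified <- classify_candidates(candidates, ann, window_5p, window_3p)
  genos <- names(genotypes)
  have_starts <- all(!vapply(coverage, function(x) is.null(x$starts),
                             logical(1)))
  abundance <- if (have_starts && length(genos) >= 1)
    quantify_candidates(candidates, coverage,
                        reference = genos[1],
                        treatment = genos[min(2, length(genos))],
                        pseudocount = pseudocount) else NULL
  anti_ids <- classified$id[classified$ncrna_class == "antisense"]
  summary <- list(
    n_candidates = nrow(candidates),
    n_antisense = sum(classified$ncrna_class == "antisense"),
    n_intergenic = sum(classified$ncrna_class == "intergenic"),
    n_rejected = sum(classified$ncrna_class == "rejected"),
    min_len = if (nrow(candidates)) min(interval_length(candidates))
      else NA,
    max_len = if (nrow(candidates)) max(interval_length(candidates))
      else NA,
    mean_len = if (nrow(candidates)) mean(interval_length(candidates))
      else NA,
    genotype_specific = setNames(lapply(genos, function(g)
      genotype_specific(candidates, g)$id), genos),
    antisense_ratio = if (!is.null(abundance) && length(genos) >= 2 &&
                          length(anti_ids))
      global_antisense_ratio(
        abundance[abundance$candidate_id %in% anti_ids, , drop = FALSE],
        reference = genos[1], treatment = genos[2]) else NA_real_)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_candidates_bed(candidates, file.path(out_dir, "candidates.bed"))
    write_classified_tsv(classified, file.path(out_dir, "classified.tsv"))
    if (requireNamespace("rtracklayer", quietly = TRUE))
      write_classified_gff3(classified,
                            file.path(out_dir, "classified.gff3"))
    if (!is.null(abundance))
      write.table(abundance, file.path(out_dir, "abundance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    s <- summary
    txt <- c(sprintf("candidates\t%d", s$n_candidates),
             sprintf("antisense\t%d", s$n_antisense),
             sprintf("intergenic\t%d", s$n_intergenic),
             sprintf("rejected\t%d", s$n_rejected),
             sprintf("size_range\t%s-%s nt (mean %s)",
                     s$min_len, s$max_len,
                     if (is.na(s$mean_len)) NA else round(s$mean_len, 1)),
             vapply(genos, function(g)
               sprintf("only_in_%s\t%d", g,
                       length(s$genotype_specific[[g]])), character(1)),
             sprintf("antisense_ratio\t%s",
                     if (is.na(s$antisense_ratio)) "NA" else
                       round(s$antisense_ratio, 3)))
    writeLines(txt, file.path(out_dir, "summary.txt"))
  }
  invisible(list(candidates = candidates, classified = classified,
                 abundance = abundance, summary = summary))
}
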