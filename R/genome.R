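## Genome model: plastome sequence, gene annotation, strand-aware queries.
## Coordinates are 1-based inclusive throughout (GenBank convention); BED
## export converts to 0-based half-open at the boundary.

FEATURE_KINDS <- c("tRNA", "rRNA", "protein", "intron", "other")
GENE_CATEGORIES <- c("photosynthesis", "gene_expression", "misc_protein",
                     "ycf", "tRNA", "rRNA")

#' Construct a plastome sequence object
#'
#' A light container for a (circular) plastid genome: its length, optional
#' residues, and the optional pair of inverted-repeat intervals. Features and
#' queries may not wrap the origin; wrap-around inputs are rejected
#' downstream.
#'
#' @param length Genome length in nucleotides (positive integer).
#' @param residues Optional nucleotide string over `A,C,G,T,N` (or a
#'   [Biostrings::DNAString]); coverage-only workflows can omit it.
#' @param circular Logical; plastomes are circular (default `TRUE`).
#' @param inverted_repeat Optional list of two `c(start, stop)` integer
#'   vectors (1-based inclusive), non-overlapping, that are
#'   reverse-complement copies of each other.
#' @return An object of class `plastome`.
#' @export
plastome <- function(length, residues = NULL, circular = TRUE,
                     inverted_repeat = NULL) {
  length <- as.integer(length)
  stopifnot(length(length) == 1L, !is.na(length), length >= 1L)
  if (!is.null(residues)) {
    residues <- as.character(residues)
    if (nchar(residues) != length)
      stop("residue count (", nchar(residues),
           ") does not match declared length (", length, ")")
    if (grepl("[^ACGTN]", residues))
      stop("residues must be over {A,C,G,T,N}")
  }
  if (!is.null(inverted_repeat)) {
    stopifnot(is.list(inverted_repeat), length(inverted_repeat) == 2L)
    ir <- lapply(inverted_repeat, function(iv) {
      iv <- as.integer(iv)
      stopifnot(length(iv) == 2L, iv[1] >= 1L, iv[2] <= length,
                iv[1] <= iv[2])
      iv
    })
    if (ir[[1]][2] >= ir[[2]][1] && ir[[2]][2] >= ir[[1]][1])
      stop("inverted repeat intervals overlap")
    inverted_repeat <- ir
  }
  structure(list(length = length, residues = residues, circular = circular,
                 inverted_repeat = inverted_repeat),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat("<plastome> length", x$length, "nt;",
      if (is.null(x$residues)) "no residues" else "with residues",
      if (!is.null(x$inverted_repeat)) sprintf(
        "; IR %d-%d / %d-%d", x$inverted_repeat[[1]][1],
        x$inverted_repeat[[1]][2], x$inverted_repeat[[2]][1],
        x$inverted_repeat[[2]][2]) else "", "\n")
  invisible(x)
}

#' Read a plastome from a FASTA file
#'
#' @param path FASTA file with a single sequence.
#' @param circular,inverted_repeat Passed to [plastome()].
#' @return A `plastome` object.
#' @export
read_plastome_fasta <- function(path, circular = TRUE,
                                inverted_repeat = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("expected exactly one sequence in ", path, ", found ", length(seqs))
  plastome(Biostrings::width(seqs)[1], as.character(seqs[[1]]),
           circular = circular, inverted_repeat = inverted_repeat)
}

#' Construct a gene annotation
#'
#' @param features A data.frame with columns `name`, `start`, `stop`,
#'   `strand` (`+`/`-`), `kind` (one of tRNA, rRNA, protein, intron, other)
#'   and optionally `category` and `cluster_id`. Missing categories are
#'   filled from `category_map` / the built-in naming heuristic.
#' @param genome_length Genome length in nt; all features must fit within.
#' @param category_map Optional named character vector (gene name ->
#'   category) consulted before the heuristic; see [load_category_map()].
#' @return An object of class `plastid_annotation` with the features sorted
#'   by start coordinate.
#' @export
annotation <- function(features, genome_length, category_map = NULL) {
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length >= 1L)
  req <- c("name", "start", "stop", "strand", "kind")
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(name = character(), start = integer(),
                           stop = integer(), strand = character(),
                           kind = character(), category = character(),
                           cluster_id = character(),
                           stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(req, names(features))
    if (length(miss)) stop("features lack columns: ",
                           paste(miss, collapse = ", "))
    features$start <- as.integer(features$start)
    features$stop <- as.integer(features$stop)
    if (any(features$start > features$stop))
      stop("feature start > stop: ",
           paste(features$name[features$start > features$stop],
                 collapse = ", "))
    if (any(features$start < 1L) || any(features$stop > genome_length))
      stop("feature outside [1, genome_length]: ",
           paste(features$name[features$start < 1L |
                               features$stop > genome_length],
                 collapse = ", "))
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (!all(features$kind %in% FEATURE_KINDS))
      stop("unknown feature kind: ",
           paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "))
    if (is.null(features$category)) features$category <- NA_character_
    fill <- is.na(features$category)
    features$category[fill] <- gene_category(features$name[fill],
                                             features$kind[fill],
                                             category_map)
    if (!all(features$category %in% GENE_CATEGORIES))
      stop("unknown category: ",
           paste(setdiff(features$category, GENE_CATEGORIES),
                 collapse = ", "))
    if (is.null(features$cluster_id)) features$cluster_id <- NA_character_
    features <- features[order(features$start, features$stop), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(genome_length = genome_length, features = features),
            class = "plastid_annotation")
}

#' @export
print.plastid_annotation <- function(x, ...) {
  cat("<plastid_annotation>", nrow(x$features), "features on a",
      x$genome_length, "nt genome\n")
  invisible(x)
}

#' Map gene names to functional categories
#'
#' Resolution order: the explicit `category_map`, then the feature kind
#' (tRNA/rRNA), then a naming heuristic covering the standard plastid gene
#' classes (psa/psb/pet/ndh/atp/rbc -> photosynthesis; rpo/rps/rpl/mat/inf
#' -> gene_expression; ycf -> ycf; otherwise misc_protein).
#'
#' @param name Character vector of gene names.
#' @param kind Matching vector of feature kinds (may be `NULL`).
#' @param category_map Optional named character vector, name -> category.
#' @return Character vector of categories.
#' @export
gene_category <- function(name, kind = NULL, category_map = NULL) {
  out <- rep(NA_character_, length(name))
  base <- sub("\\.[0-9]+$", "", sub("-?[0-9]+$", "", name))
  if (!is.null(category_map)) {
    hit <- name %in% names(category_map)
    out[hit] <- unname(category_map[name[hit]])
    hit2 <- is.na(out) & base %in% names(category_map)
    out[hit2] <- unname(category_map[base[hit2]])
  }
  if (!is.null(kind)) {
    out[is.na(out) & kind == "tRNA"] <- "tRNA"
    out[is.na(out) & kind == "rRNA"] <- "rRNA"
  }
  todo <- is.na(out)
  pick <- function(pat, cat) {
    sel <- todo & grepl(pat, name)
    out[sel] <<- cat
    todo[sel] <<- FALSE
  }
  pick("^trn", "tRNA")
  pick("^rrn", "rRNA")
  pick("^(psa|psb|pet|ndh|atp|rbc)", "photosynthesis")
  pick("^(rpo|rps|rpl|mat|inf)", "gene_expression")
  pick("^ycf", "ycf")
  out[todo] <- "misc_protein"
  out
}

#' Load a gene -> category map from a two-column text config
#'
#' @param path Tab-separated file with columns `gene_name` and `category`
#'   (header optional). The package ships a default under
#'   `system.file("extdata", "gene_categories.tsv", package = "plastidnc")`.
#' @return Named character vector suitable for [annotation()].
#' @export
load_category_map <- function(path = system.file("extdata",
                                                 "gene_categories.tsv",
                                                 package = "plastidnc")) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!all(c("gene_name", "category") %in% names(tab)))
    stop("category map needs columns gene_name, category")
  bad <- setdiff(unique(tab$category), GENE_CATEGORIES)
  if (length(bad)) stop("unknown categories in map: ",
                        paste(bad, collapse = ", "))
  setNames(tab$category, tab$gene_name)
}

gff3_types <- c(gene = "protein", tRNA = "tRNA", rRNA = "rRNA",
                intron = "intron", tRNA_gene = "tRNA", rRNA_gene = "rRNA")

#' Load a gene annotation from GFF3
#'
#' Accepts `gene`, `tRNA`, `rRNA` and `intron` records (1-based inclusive
#' coordinates per the GFF3 standard); other record types are ignored. A
#' `kind` attribute, when present, overrides the type-derived kind;
#' `category` and `cluster_id` attributes are honoured. The declared
#' `##sequence-region` length is used unless `genome_length` is given.
#'
#' @param path GFF3 file.
#' @param genome_length Optional genome length; overrides the
#'   `##sequence-region` directive.
#' @param category_map Optional named vector, see [annotation()].
#' @return A `plastid_annotation`.
#' @export
load_annotation <- function(path, genome_length = NULL, category_map = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 input requires the rtracklayer package")
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    lineno <- which(body)[which(nf != 9L)[1]]
    stop("malformed GFF3 line ", lineno, " in ", path,
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1])
  }
  if (is.null(genome_length)) {
    sr <- grep("^##sequence-region", lines, value = TRUE)
    if (length(sr)) {
      genome_length <- as.integer(strsplit(trimws(sr[1]), "\\s+")[[1]][4])
    } else if (any(body)) {
      stop("no ##sequence-region directive; supply genome_length")
    } else genome_length <- 1L
  }
  if (!any(body))
    return(annotation(NULL, genome_length, category_map))
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% names(gff3_types)
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  getattr <- function(col) {
    if (col %in% names(md)) as.character(md[[col]]) else
      rep(NA_character_, length(gr))
  }
  nm <- getattr("ID")
  alt <- getattr("Name")
  nm[is.na(nm)] <- alt[is.na(nm)]
  if (anyNA(nm)) stop("GFF3 feature without ID or Name attribute")
  kind <- getattr("kind")
  kind[is.na(kind)] <- unname(gff3_types[as.character(gr$type)[is.na(kind)]])
  feats <- data.frame(
    name = nm,
    start = GenomicRanges::start(gr),
    stop = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    category = getattr("category"),
    cluster_id = getattr("cluster_id"),
    stringsAsFactors = FALSE)
  if (any(feats$stop > genome_length))
    stop("feature beyond declared genome length (", genome_length, "): ",
         paste(feats$name[feats$stop > genome_length], collapse = ", "))
  annotation(feats, genome_length, category_map)
}

#' Write a gene annotation as GFF3
#'
#' Inverse of [load_annotation()]: kinds map to GFF3 types (protein/other ->
#' `gene`) and `kind`, `category`, `cluster_id` are stored as attributes so
#' the round trip is exact.
#'
#' @param ann A `plastid_annotation`.
#' @param path Output file.
#' @param seqname Sequence name to write (default `"plastome"`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, seqname = "plastome") {
  stopifnot(inherits(ann, "plastid_annotation"))
  for (p in c("rtracklayer", "GenomeInfoDb"))
    if (!requireNamespace(p, quietly = TRUE))
      stop("GFF3 output requires the ", p, " package")
  f <- ann$features
  type <- c(tRNA = "tRNA", rRNA = "rRNA", intron = "intron",
            protein = "gene", other = "gene")[f$kind]
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(f$start, f$stop),
    strand = f$strand,
    type = unname(type), source = "plastidnc",
    ID = f$name, kind = f$kind, category = f$category,
    cluster_id = f$cluster_id,
    seqinfo = GenomeInfoDb::Seqinfo(seqname, ann$genome_length))
  rtracklayer::export(gr, path, format = "gff3")
  lines <- readLines(path)
  if (!any(startsWith(lines, "##sequence-region"))) {
    directive <- paste("##sequence-region", seqname, 1, ann$genome_length)
    writeLines(append(lines, directive, after = 1L), path)
  }
  invisible(path)
}

#' Strand-aware overlap query against an annotation
#'
#' Returns exactly the features whose interval intersects `[start, stop]` by
#' at least one nucleotide and whose strand satisfies `strand_mode`, ordered
#' by start.
#'
#' @param ann A `plastid_annotation`.
#' @param start,stop Query interval, 1-based inclusive, within the genome.
#' @param strand_mode One of `"both"`, `"same:+"`, `"same:-"`,
#'   `"opposite-of:+"`, `"opposite-of:-"`. `same:S` keeps features on strand
#'   `S`; `opposite-of:S` keeps features opposite a query on strand `S`.
#' @return The matching rows of `ann$features`.
#' @export
features_overlapping <- function(ann, start, stop, strand_mode = "both") {
  stopifnot(inherits(ann, "plastid_annotation"))
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start > stop)
    stop("invalid query interval: start must be <= stop")
  if (start < 1L || stop > ann$genome_length)
    stop("query outside [1, genome_length]")
  f <- ann$features
  if (nrow(f) == 0L) return(f)
  want <- switch(strand_mode,
                 "both" = c("+", "-"),
                 "same:+" = "+", "same:-" = "-",
                 "opposite-of:+" = "-", "opposite-of:-" = "+",
                 stop("unknown strand_mode: ", strand_mode))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start, stop),
    IRanges::IRanges(f$start, f$stop))
  idx <- S4Vectors::subjectHits(hits)
  idx <- idx[f$strand[idx] %in% want]
  f[sort(idx), , drop = FALSE]
}
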