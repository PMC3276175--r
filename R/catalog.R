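## The packaged reference catalog: 107 chloroplast ncRNA candidates with
## coordinates, strand, RT-PCR and RNA gel blot results. Band lists are
## comma-separated sizes in kb; "-" means tested with no visible band, "NT"
## not tested (untested RT-PCR implies untested blots).

#' Path to the packaged ncRNA catalog
#'
#' @return Path to the 107-row candidate catalog TSV shipped with the
#'   package.
#' @export
catalog_path <- function() {
  system.file("extdata", "ncrna_catalog.tsv", package = "plastidnc",
              mustWork = TRUE)
}

#' Load a candidate catalog
#'
#' @param path Catalog TSV with columns `ordinal`, `designation`, `start`,
#'   `stop`, `strand`, `rtpcr` (`+`/`-`/`NT`), `wt_bands`, `pnp_bands`
#'   (comma-separated kb sizes, `-` for none, `NT` for untested). Defaults
#'   to the packaged catalog.
#' @return `data.frame` of class `ncrna_catalog` with list-columns
#'   `wt_bands` / `pnp_bands` (numeric kb sizes; qualitative entries such
#'   as smears are kept as `NA` sizes but still count as detections) and
#'   logical columns `rtpcr_tested`, `rtpcr_positive`, `blot_tested`,
#'   `blot_detected`.
#' @export
load_catalog <- function(path = catalog_path()) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("ordinal", "designation", "start", "stop", "strand", "rtpcr",
            "wt_bands", "pnp_bands")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("catalog lacks columns: ",
                         paste(miss, collapse = ", "))
  cat_ <- data.frame(ordinal = as.integer(raw$ordinal),
                     designation = raw$designation,
                     start = as.integer(raw$start),
                     stop = as.integer(raw$stop),
                     strand = raw$strand, rtpcr = raw$rtpcr,
                     stringsAsFactors = FALSE)
  bad <- which(is.na(cat_$ordinal) | is.na(cat_$start) | is.na(cat_$stop) |
                 cat_$start >= cat_$stop | !cat_$strand %in% c("+", "-") |
                 !cat_$rtpcr %in% c("+", "-", "NT"))
  if (length(bad))
    stop("malformed catalog row(s), ordinal: ",
         paste(head(raw$ordinal[bad], 5), collapse = ", "))
  if (anyDuplicated(cat_$ordinal))
    stop("duplicate ordinal: ",
         paste(unique(cat_$ordinal[duplicated(cat_$ordinal)]),
               collapse = ", "))
  parse_bands <- function(x, ordinal) {
    if (x == "NT") return(NULL)
    if (x %in% c("-", "", "\u2014")) return(numeric())
    toks <- trimws(strsplit(x, ",")[[1]])
    sizes <- suppressWarnings(as.numeric(toks))
    sizes # qualitative tokens (smears) -> NA size, still a detection
  }
  cat_$wt_bands <- lapply(seq_len(nrow(raw)), function(i)
    parse_bands(raw$wt_bands[i], raw$ordinal[i]))
  cat_$pnp_bands <- lapply(seq_len(nrow(raw)), function(i)
    parse_bands(raw$pnp_bands[i], raw$ordinal[i]))
  cat_$wt_bands_raw <- raw$wt_bands
  cat_$pnp_bands_raw <- raw$pnp_bands
  cat_$rtpcr_tested <- cat_$rtpcr != "NT"
  cat_$rtpcr_positive <- cat_$rtpcr == "+"
  cat_$blot_tested <- !vapply(cat_$wt_bands, is.null, logical(1)) |
    !vapply(cat_$pnp_bands, is.null, logical(1))
  nb <- function(b) if (is.null(b)) 0L else length(b)
  cat_$blot_detected <- vapply(cat_$wt_bands, nb, integer(1)) +
    vapply(cat_$pnp_bands, nb, integer(1)) > 0
  inconsistent <- !cat_$rtpcr_tested & cat_$blot_tested
  if (any(inconsistent))
    stop("catalog row with untested RT-PCR but tested blot, ordinal: ",
         paste(cat_$ordinal[inconsistent], collapse = ", "))
  class(cat_) <- c("ncrna_catalog", "data.frame")
  cat_
}

#' Write a catalog in the packaged TSV dialect
#'
#' Exact inverse of [load_catalog()] for round-tripping.
#'
#' @param cat_ An `ncrna_catalog`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat_, path) {
  out <- data.frame(ordinal = cat_$ordinal, designation = cat_$designation,
                    start = cat_$start, stop = cat_$stop,
                    strand = cat_$strand, rtpcr = cat_$rtpcr,
                    wt_bands = cat_$wt_bands_raw,
                    pnp_bands = cat_$pnp_bands_raw)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Catalog summary statistics
#'
#' Class is inferred from the designation: an `int` suffix marks an
#' intergenic (within-cluster) ncRNA; an `i` suffix (before any ordinal)
#' marks an antisense-to-intron candidate, counted within antisense.
#' Lengths use the endpoint difference `stop - start` (the convention under
#' which the catalog's printed minimum and mean are reproduced);
#' `mean_len_inclusive` reports `stop - start + 1`. Blot detection means at
#' least one band in either genotype.
#'
#' @param cat_ An `ncrna_catalog` from [load_catalog()].
#' @return A list of class `catalog_stats`: `n_total`, `n_antisense`,
#'   `n_intergenic`, `n_intronic`, `min_len`, `max_len`, `mean_len`,
#'   `mean_len_inclusive`, `n_rtpcr_tested`, `n_rtpcr_positive`,
#'   `n_blot_detected`.
#' @export
catalog_statistics <- function(cat_) {
  stopifnot(nrow(cat_) >= 1L)
  intergenic <- grepl("int(-[0-9]+)?$", cat_$designation)
  intronic <- !intergenic & grepl("i(-[0-9]+)?$", cat_$designation)
  len <- cat_$stop - cat_$start
  stats <- list(n_total = nrow(cat_),
                n_antisense = sum(!intergenic),
                n_intergenic = sum(intergenic),
                n_intronic = sum(intronic),
                min_len = min(len), max_len = max(len),
                mean_len = mean(len),
                mean_len_inclusive = mean(len + 1),
                n_rtpcr_tested = sum(cat_$rtpcr_tested),
                n_rtpcr_positive = sum(cat_$rtpcr_positive),
                n_blot_detected = sum(cat_$blot_detected))
  stopifnot(stats$n_antisense + stats$n_intergenic == stats$n_total,
            stats$n_rtpcr_positive <= stats$n_rtpcr_tested,
            stats$n_blot_detected <= stats$n_rtpcr_positive)
  class(stats) <- "catalog_stats"
  stats
}

#' @export
print.catalog_stats <- function(x, ...) {
  cat("<catalog_stats>\n",
      sprintf("  candidates: %d (%d antisense, %d intergenic; %d opposite introns)\n",
              x$n_total, x$n_antisense, x$n_intergenic, x$n_intronic),
      sprintf("  length (stop - start): %d-%d nt, mean %.1f (inclusive mean %.1f)\n",
              x$min_len, x$max_len, x$mean_len, x$mean_len_inclusive),
      sprintf("  RT-PCR: %d tested, %d positive; gel blot: %d detected\n",
              x$n_rtpcr_tested, x$n_rtpcr_positive, x$n_blot_detected),
      sep = "")
  invisible(x)
}
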