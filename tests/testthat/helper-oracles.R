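# Independent brute-force oracles. These deliberately use different
# algorithms from the implementations they check.

# O(n) scan over all features, no interval index
oracle_overlap <- function(features, qstart, qstop, strands) {
  hit <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    hit[i] <- f$start <= qstop && f$stop >= qstart && f$strand %in% strands
  }
  features[hit, , drop = FALSE]
}

# per-base recount of depth/start tracks by explicit looping
oracle_coverage <- function(pl, genome_length, multi_weight = 1) {
  tr <- list("+" = list(depth = numeric(genome_length),
                        starts = numeric(genome_length)),
             "-" = list(depth = numeric(genome_length),
                        starts = numeric(genome_length)))
  for (i in seq_len(nrow(pl))) {
    w <- if (pl$n_placements[i] == 2L) multi_weight else 1
    s <- pl$strand[i]
    tr[[s]]$depth[pl$start[i]:pl$stop[i]] <-
      tr[[s]]$depth[pl$start[i]:pl$stop[i]] + w
    tr[[s]]$starts[pl$start[i]] <- tr[[s]]$starts[pl$start[i]] + w
  }
  tr
}

# run enumeration from thresholded positions (no rle)
oracle_runs <- function(depth, peak_threshold = 50, end_threshold = 10) {
  above <- which(depth >= end_threshold)
  if (!length(above))
    return(data.frame(start = integer(), stop = integer(),
                      max_depth = numeric()))
  grp <- cumsum(c(1L, as.integer(diff(above) != 1L)))
  out <- do.call(rbind, lapply(split(above, grp), function(p) {
    if (max(depth[p]) >= peak_threshold)
      data.frame(start = min(p), stop = max(p), max_depth = max(depth[p]))
  }))
  if (is.null(out))
    return(data.frame(start = integer(), stop = integer(),
                      max_depth = numeric()))
  rownames(out) <- NULL
  out
}

# candidate unification rule re-implemented directly on two genotype tracks
oracle_two_track <- function(depth_by_geno, cfg, priority) {
  runs <- lapply(depth_by_geno, oracle_runs, cfg$peak_threshold,
                 cfg$end_threshold)
  all_r <- do.call(rbind, Map(function(r, g)
    if (nrow(r)) cbind(r, genotype = g) else NULL, runs, names(runs)))
  if (is.null(all_r)) return(NULL)
  # connected components by overlap, quadratic
  n <- nrow(all_r)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          all_r$start[i] <= all_r$stop[j] &&
          all_r$stop[i] >= all_r$start[j]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- NULL
  for (k in unique(comp)) {
    grp <- all_r[comp == k, , drop = FALSE]
    src <- priority[priority %in% grp$genotype][1]
    sr <- grp[grp$genotype == src, , drop = FALSE]
    for (j in seq_len(nrow(sr))) {
      span <- sr$start[j]:sr$stop[j]
      trig <- names(depth_by_geno)[vapply(depth_by_geno, function(d)
        max(d[span]) >= cfg$peak_threshold, logical(1))]
      out <- rbind(out, data.frame(start = sr$start[j], stop = sr$stop[j],
                                   end_source = src,
                                   trigger = paste(trig, collapse = ",")))
    }
  }
  out[order(out$start), , drop = FALSE]
}

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# positional brute force: test every position and frame
oracle_orfs <- function(seq, min_aa = 20) {
  n <- nchar(seq)
  codon <- function(i) substr(seq, i, i + 2L)
  out <- NULL
  for (i in seq_len(max(0, n - 5L))) {
    if (codon(i) != "ATG") next
    # first start of its stop-delimited segment?
    j <- i - 3L; first <- TRUE
    while (j >= 1L) {
      cj <- codon(j)
      if (cj %in% ORACLE_STOPS) break
      if (cj == "ATG") { first <- FALSE; break }
      j <- j - 3L
    }
    if (!first) next
    k <- i + 3L; found <- FALSE
    while (k + 2L <= n) {
      if (codon(k) %in% ORACLE_STOPS) { found <- TRUE; break }
      k <- k + 3L
    }
    if (!found) next
    aa <- (k - i) %/% 3L
    if (aa >= min_aa)
      out <- rbind(out, data.frame(offset_start = i, offset_stop = k + 2L,
                                   aa_length = aa,
                                   frame = (i - 1L) %% 3L + 1L))
  }
  if (is.null(out))
    return(data.frame(offset_start = integer(), offset_stop = integer(),
                      aa_length = integer(), frame = integer()))
  out <- out[order(out$offset_start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# iterative pairwise merge to a fixpoint
oracle_merge <- function(iv, max_gap) {
  iv <- iv[order(iv$start), , drop = FALSE]
  repeat {
    done <- TRUE
    i <- 1L
    while (i < nrow(iv)) {
      if (iv$start[i + 1] - iv$stop[i] - 1 <= max_gap) {
        iv$stop[i] <- max(iv$stop[i], iv$stop[i + 1])
        iv <- iv[-(i + 1), , drop = FALSE]
        done <- FALSE
      } else i <- i + 1L
    }
    if (done) return(iv)
  }
}

# small two-genotype coverage fixture from explicit tracks
cov2 <- function(dp, dm, sp = NULL, sm = NULL) {
  stranded_coverage(dp, dm, sp, sm)
}
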