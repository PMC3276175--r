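test_that("caller_config enforces threshold ordering", {
  cfg <- caller_config()
  expect_equal(cfg$peak_threshold, 50)
  expect_equal(cfg$end_threshold, 10)
  expect_error(caller_config(peak_threshold = 5, end_threshold = 10))
})

test_that("call_strand_candidates applies the trigger/end rule literally", {
  cfg <- caller_config()
  expect_equal(nrow(call_strand_candidates(rep(0, 500), cfg)), 0L)
  expect_equal(nrow(call_strand_candidates(numeric(), cfg)), 0L)
  d <- numeric(300); d[100:199] <- 60
  expect_equal(call_strand_candidates(d, cfg),
               data.frame(start = 100L, stop = 199L, max_depth = 60))
  # a run at exactly the end threshold belongs; depth 9 terminates it;
  # peak at exactly 50 triggers (inclusive reading)
  d2 <- c(rep(20, 50), rep(55, 10), rep(12, 60), 5, rep(60, 79))
  got <- call_strand_candidates(d2, cfg)
  expect_equal(got, data.frame(start = c(1L, 122L), stop = c(120L, 200L),
                               max_depth = c(55, 60)))
  d3 <- numeric(100); d3[40:60] <- 10; d3[50] <- 50
  expect_equal(call_strand_candidates(d3, cfg),
               data.frame(start = 40L, stop = 60L, max_depth = 50))
  d3[50] <- 49
  expect_equal(nrow(call_strand_candidates(d3, cfg)), 0L)
  expect_error(call_strand_candidates(c(1, -1, 3), cfg), ">= 0")
})

test_that("call_strand_candidates equals run enumeration on random tracks", {
  set.seed(101)
  cfg <- caller_config()
  for (rep in 1:150) {
    d <- sample(0:100, sample(20:600, 1), replace = TRUE)
    expect_equal(call_strand_candidates(d, cfg), oracle_runs(d),
                 ignore_attr = TRUE)
  }
})

test_that("thresholds act monotonically on candidate count and span", {
  set.seed(13)
  d <- rpois(2000, 12) + sample(c(0, 60), 2000, TRUE, c(.95, .05))
  n_prev <- Inf
  for (pk in c(30, 50, 80)) {
    n <- nrow(call_strand_candidates(d, caller_config(pk, 10)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  wide <- call_strand_candidates(d, caller_config(50, 5))
  narrow <- call_strand_candidates(d, caller_config(50, 10))
  for (i in seq_len(nrow(narrow))) {
    covering <- wide$start <= narrow$start[i] & wide$stop >= narrow$stop[i]
    expect_true(any(covering)) # lowering the end threshold only widens
  }
})

test_that("call_candidates unifies genotypes with end-source precedence", {
  glen <- 400
  dW <- numeric(glen); dW[100:200] <- 60
  dM <- numeric(glen); dM[95:230] <- 70
  covs <- list(WT = cov2(dW, numeric(glen)), "pnp1-1" = cov2(dM, numeric(glen)))
  got <- call_candidates(covs)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 100L)
  expect_equal(got$stop, 200L)
  expect_equal(got$end_source, "WT")
  expect_true(grepl("WT", got$trigger_genotypes))
  validate_candidates(got, covs)

  # single genotype lifts strand runs directly
  one <- call_candidates(list(WT = cov2(dW, numeric(glen))))
  expect_equal(one$start, 100L)
  expect_equal(one$stop, 200L)
  expect_equal(one$end_source, "WT")

  # mutant-only peak: WT stays at 30
  dW2 <- numeric(glen); dW2[150:180] <- 30
  dM2 <- numeric(glen); dM2[140:190] <- 90
  got2 <- call_candidates(list(WT = cov2(dW2, numeric(glen)),
                               "pnp1-1" = cov2(dM2, numeric(glen))))
  expect_equal(got2$trigger_genotypes, "pnp1-1")
  expect_equal(got2$end_source, "pnp1-1")
  expect_equal(c(got2$start, got2$stop), c(140L, 190L))

  expect_error(call_candidates(list(WT = cov2(dW, numeric(glen)),
                                    M = cov2(numeric(10), numeric(10)))),
               "genome length")
})

test_that("two-genotype calling matches the brute-force unification rule", {
  set.seed(17)
  cfg <- caller_config()
  for (rep in 1:60) {
    glen <- 500
    mk <- function() {
      d <- rpois(glen, 6)
      for (k in seq_len(sample(0:4, 1))) {
        a <- sample(glen - 60, 1)
        d[a:(a + sample(20:60, 1))] <- sample(40:90, 1)
      }
      d
    }
    tracks <- list(WT = mk(), "pnp1-1" = mk())
    covs <- list(WT = cov2(tracks$WT, numeric(glen)),
                 "pnp1-1" = cov2(tracks[["pnp1-1"]], numeric(glen)))
    got <- call_candidates(covs, cfg)
    want <- oracle_two_track(tracks, cfg, c("WT", "pnp1-1"))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$stop, want$stop)
      expect_equal(got$end_source, want$end_source)
      expect_equal(got$trigger_genotypes, want$trigger)
      validate_candidates(got, covs, cfg)
    }
  }
})

test_that("merge_adjacent bridges small gaps and is a fixpoint merge", {
  glen <- 600
  d <- numeric(glen); d[100:200] <- 60; d[203:300] <- 70; d[400:450] <- 55
  covs <- list(WT = cov2(d, numeric(glen)))
  cand <- call_candidates(covs)
  expect_equal(nrow(cand), 3L)
  expect_identical(merge_adjacent(cand, 0), cand)
  m5 <- merge_adjacent(cand, 5)
  expect_equal(m5$start[1], 100L)
  expect_equal(m5$stop[1], 300L)
  expect_equal(m5$max_depth[[1]][["WT"]], 70)
  expect_equal(nrow(m5), 2L)
  set.seed(23)
  for (rep in 1:20) {
    starts <- sort(sample(2000, 8))
    iv <- data.frame(start = starts, stop = starts + sample(10:80, 8, TRUE))
    iv <- oracle_merge(iv, 0) # normalise raw overlaps first
    cand <- data.frame(id = sprintf("c%d", seq_len(nrow(iv))),
                       start = iv$start, stop = iv$stop, strand = "+",
                       end_source = "WT", trigger_genotypes = "WT")
    cand$max_depth <- rep(list(c(WT = 60)), nrow(iv))
    class(cand) <- c("ncrna_candidates", "data.frame")
    n_prev <- Inf
    for (gap in c(0, 10, 50)) {
      got <- merge_adjacent(cand, gap)
      want <- oracle_merge(iv, gap)
      expect_equal(got$start, want$start)
      expect_equal(got$stop, want$stop)
      expect_lte(nrow(got), n_prev)
      n_prev <- nrow(got)
    }
  }
})

test_that("interval length conventions reproduce the catalog arithmetic", {
  cand <- data.frame(start = c(74136, 7611, 5), stop = c(74184, 7691, 5))
  expect_equal(interval_length(cand), c(48L, 80L, 0L))
  expect_equal(interval_span(cand), c(49L, 81L, 1L))
})

test_that("BED export is 0-based half-open with capped scores", {
  glen <- 300
  d <- numeric(glen); d[50:120] <- 1500
  cand <- call_candidates(list(WT = cov2(d, numeric(glen))))
  path <- withr::local_tempfile(fileext = ".bed")
  write_candidates_bed(cand, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 49)
  expect_equal(bed$V3, 120)
  expect_equal(bed$V5, 1000)
  expect_equal(bed$V6, "+")
})
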