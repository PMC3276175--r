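small_cfg <- function(...) {
  genes <- data.frame(name = "geneA", start = 1000, stop = 2200,
                      strand = "+", kind = "protein",
                      cluster_id = NA_character_)
  simulation_config(
    genome_length = 5000, gene_layout = genes,
    sense_expression = c(geneA = 60),
    antisense_units = data.frame(name = "as-geneA", start = 1300,
                                 stop = 1700, strand = "-",
                                 mean_copies = 30,
                                 has_own_promoter = TRUE),
    genotype_effects = list(WT = list(antisense_amplification = 1,
                                      three_prime_extension = 0)),
    end_suppression = list(prob_structured_end = 0, suppressed_span = 40),
    depth_target = 4000, ...)
}

test_that("build_toy_plastome is deterministic and label-consistent", {
  cfg <- simulation_config()
  a <- build_toy_plastome(cfg, seed = 7)
  b <- build_toy_plastome(cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$genome$residues,
                         build_toy_plastome(cfg, seed = 8)$genome$residues))
  expect_equal(a$genome$length, 50000L)
  # class labels consistent with the layout
  expect_setequal(a$truth$class[a$truth$name == "nc-psbB-psbHint"],
                  "intergenic")
  expect_true(all(a$truth$class[grepl("^as-", a$truth$name)] == "antisense"))
  expect_equal(sum(a$truth$class == "sense"), nrow(cfg$gene_layout))
  # all planted units within the genome
  expect_true(all(a$truth$start >= 1 & a$truth$stop <= 50000))
})

test_that("no antisense units leaves sense-only ground truth", {
  cfg <- simulation_config(
    antisense_units = data.frame(name = character(), start = integer(),
                                 stop = integer(), strand = character(),
                                 mean_copies = numeric(),
                                 has_own_promoter = logical()))
  toy <- build_toy_plastome(cfg, seed = 3)
  expect_true(all(toy$truth$class == "sense"))
})

test_that("random configurations keep planted units in bounds", {
  set.seed(71)
  for (rep in 1:10) {
    glen <- sample(8000:20000, 1)
    gs <- sample(1000:3000, 1)
    genes <- data.frame(name = "g1", start = gs, stop = gs + 1200,
                        strand = "+", kind = "protein",
                        cluster_id = NA_character_)
    us <- sample(gs:(gs + 800), 1)
    cfg <- simulation_config(
      genome_length = glen, gene_layout = genes,
      sense_expression = c(g1 = 50),
      antisense_units = data.frame(name = "u1", start = us,
                                   stop = us + 300, strand = "-",
                                   mean_copies = 20,
                                   has_own_promoter = TRUE),
      genotype_effects = list(WT = list(antisense_amplification = 1,
                                        three_prime_extension = 0)),
      depth_target = 1000)
    toy <- build_toy_plastome(cfg, seed = rep)
    expect_true(all(toy$truth$start >= 1 & toy$truth$stop <= glen))
    pl <- simulate_placements(toy$truth, cfg, "WT", seed = rep)
    expect_true(all(pl$start >= 1 & pl$stop <= glen))
  }
})

test_that("overlapping same-strand genes are rejected", {
  genes <- data.frame(name = c("a", "b"), start = c(100, 500),
                      stop = c(600, 900), strand = "+", kind = "protein",
                      cluster_id = NA_character_)
  expect_error(simulation_config(genome_length = 2000, gene_layout = genes,
                                 sense_expression = c(a = 1, b = 1)),
               "overlapping")
})

test_that("simulated placements are seeded, bounded and strand-faithful", {
  cfg <- small_cfg()
  toy <- build_toy_plastome(cfg, seed = 5)
  p1 <- simulate_placements(toy$truth, cfg, "WT", seed = 9)
  p2 <- simulate_placements(toy$truth, cfg, "WT", seed = 9)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 4000L)
  # depth_target 0 -> empty
  cfg0 <- small_cfg(); cfg0$depth_target <- 0L
  expect_equal(nrow(simulate_placements(toy$truth, cfg0, "WT", 1)), 0L)
  expect_error(simulate_placements(toy$truth, cfg, "rnr1", 1),
               "unknown genotype")
  # minus-strand reads only over the antisense unit, plus-strand over the
  # gene (with read-through and jitter slack)
  minus <- p1[p1$strand == "-", ]
  expect_true(all(minus$start >= 1300 - cfg$terminus_jitter))
  expect_true(all(minus$stop <= 1700 + cfg$terminus_jitter))
  plus <- p1[p1$strand == "+", ]
  expect_true(all(plus$start >= 1000 - cfg$terminus_jitter))
  expect_true(all(plus$stop <= 2200 + cfg$terminus_jitter + 2500))
  expect_true(all(p1$stop - p1$start + 1 <= cfg$read_length))
  expect_true(all(p1$stop - p1$start + 1 >= 1))
})

test_that("a no-read-through gene confines reads to its span", {
  cfg <- small_cfg(read_through_prob = 0, terminus_jitter = 0)
  toy <- build_toy_plastome(cfg, seed = 5)
  pl <- simulate_placements(toy$truth, cfg, "WT", seed = 9)
  plus <- pl[pl$strand == "+", ]
  expect_true(all(plus$start >= 1000 & plus$stop <= 2200))
})

test_that("evaluate_recovery scores matches, misses and fragmentation", {
  truth <- data.frame(name = c("u1", "u2"), start = c(100, 1000),
                      stop = c(499, 1399), strand = "-",
                      class = "antisense")
  exact <- data.frame(start = truth$start, stop = truth$stop, strand = "-")
  ev <- evaluate_recovery(exact, truth)
  expect_equal(ev$precision, 1, ignore_attr = TRUE)
  expect_equal(ev$recall, 1)
  expect_equal(ev$fragmentation_ratio, 1)
  # no candidates: precision 1 with flag, recall 0
  none <- evaluate_recovery(exact[0, ], truth)
  expect_equal(ev$precision, 1, ignore_attr = TRUE)
  expect_true(isTRUE(attr(none$precision, "no_candidates")))
  expect_equal(none$recall, 0)
  expect_true(is.na(none$fragmentation_ratio))
  # hand-computed Jaccard splits of a 400 nt unit (u1: 100-499)
  splits <- list(
    list(cand = data.frame(start = c(100, 300), stop = c(299, 499),
                           strand = "-"),
         jac = c(0.5, 0.5), rec = TRUE), # halves: 200/400 each
    list(cand = data.frame(start = c(100, 340), stop = c(259, 499),
                           strand = "-"),
         jac = c(0.4, 0.4), rec = FALSE), # 160/400 each: no match
    list(cand = data.frame(start = 100, stop = 379, strand = "-"),
         jac = 0.7, rec = TRUE), # 280/400
    list(cand = data.frame(start = 80, stop = 519, strand = "-"),
         jac = 400 / 440, rec = TRUE), # overhang both sides
    list(cand = data.frame(start = 100, stop = 499, strand = "+"),
         jac = 0, rec = FALSE)) # wrong strand
  for (sp in splits) {
    ev <- evaluate_recovery(sp$cand, truth[1, , drop = FALSE])
    expect_equal(ev$recall, as.numeric(sp$rec))
    for (i in seq_len(nrow(sp$cand))) {
      got <- plastidnc:::interval_jaccard(sp$cand$start[i], sp$cand$stop[i],
                                          100, 499)
      if (sp$cand$strand[i] == "-") expect_equal(got, sp$jac[i])
    }
  }
  # split into two half-matching candidates: ratio 2 / 1
  ev2 <- evaluate_recovery(splits[[1]]$cand, truth[1, , drop = FALSE])
  expect_equal(ev2$fragmentation_ratio, 2)
})

test_that("expected_unit_depth tracks realised coverage within ~40%", {
  cfg <- small_cfg(terminus_jitter = 0, read_through_prob = 0)
  toy <- build_toy_plastome(cfg, seed = 5)
  exp_d <- expected_unit_depth(toy$truth, cfg, "WT")
  pl <- simulate_placements(toy$truth, cfg, "WT", seed = 13)
  cov <- coverage_from_placements(pl, cfg$genome_length)
  got <- mean(cov$depth[["-"]][1350:1650])
  expect_gt(got, exp_d[["as-geneA"]] * 0.6)
  expect_lt(got, exp_d[["as-geneA"]] * 1.8)
})
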