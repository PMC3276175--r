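mk_cand <- function(start, stop, strand, id = sprintf("c%03d",
                                                      seq_along(start))) {
  out <- data.frame(id = id, start = start, stop = stop, strand = strand,
                    end_source = rep("WT", length(start)),
                    trigger_genotypes = rep("WT", length(start)),
                    stringsAsFactors = FALSE)
  out$max_depth <- rep(list(c(WT = 60)), nrow(out))
  class(out) <- c("ncrna_candidates", "data.frame")
  out
}

cluster_ann <- function() {
  annotation(data.frame(
    name = c("G1", "G2"), start = c(100, 600), stop = c(400, 900),
    strand = "+", kind = "protein", cluster_id = "opA"), 1000)
}

test_that("classify partitions candidates into antisense/intergenic/rejected", {
  ann <- cluster_ann()
  cls <- classify_candidates(mk_cand(c(150, 450, 150, 20),
                                     c(300, 520, 300, 60),
                                     c("-", "-", "+", "+")), ann)
  expect_equal(cls$ncrna_class,
               c("antisense", "intergenic", "rejected", "rejected"))
  expect_equal(cls$targets[1], "G1")
  expect_equal(cls$targets[2], "G1,G2") # both flanking cluster genes
  expect_equal(cls$reject_reason[3], "same_strand_overlap")
  expect_equal(cls$reject_reason[4], "unassigned")
  # every candidate lands in exactly one class
  expect_true(all(cls$ncrna_class %in%
                    c("antisense", "intergenic", "rejected")))
})

test_that("antisense wins over intergenic when both apply", {
  ann <- cluster_ann()
  # overlaps G1 (opposite strand) and extends into the cluster gap
  cls <- classify_candidates(mk_cand(350, 500, "-"), ann)
  expect_equal(cls$ncrna_class, "antisense")
  expect_equal(cls$principal_target, "G1")
})

test_that("pairing_region is orientation-aware and covers spec examples", {
  expect_equal(pairing_region(90, 150, "-", 100, 400, "+", 0, 0),
               "five_prime")
  expect_equal(pairing_region(150, 300, "-", 100, 400, "+", 0, 0),
               "internal")
  expect_equal(pairing_region(380, 420, "-", 100, 400, "+", 0, 0),
               "three_prime")
  expect_setequal(pairing_region(50, 450, "-", 100, 400, "+", 0, 0),
                  c("five_prime", "three_prime"))
  # on a minus-strand gene the 5' terminus is the stop coordinate
  expect_equal(pairing_region(380, 420, "+", 100, 400, "-", 0, 0),
               "five_prime")
  expect_error(pairing_region(1, 10, "+", 5, 20, "+"), "opposite")
})

test_that("pairing_region equals the window-overlap oracle and is symmetric", {
  set.seed(31)
  glen <- 1000
  for (rep in 1:200) {
    gs <- sample(200:700, 1); ge <- gs + sample(50:250, 1)
    cs <- sample(glen - 100, 1); ce <- cs + sample(20:150, 1)
    gstrand <- sample(c("+", "-"), 1)
    cstrand <- if (gstrand == "+") "-" else "+"
    w <- sample(c(0, 25), 1)
    got <- pairing_region(cs, ce, cstrand, gs, ge, gstrand, w, w)
    p5 <- if (gstrand == "+") gs else ge
    p3 <- if (gstrand == "+") ge else gs
    want <- character()
    if (ce >= p5 - w && cs <= p5 + w) want <- c(want, "five_prime")
    if (ce >= p3 - w && cs <= p3 + w) want <- c(want, "three_prime")
    if (!length(want) && ce >= gs && cs <= ge) want <- "internal"
    expect_setequal(got, want)
    # reflection through the genome midpoint with strand swap
    refl <- pairing_region(glen - ce + 1, glen - cs + 1, gstrand,
                           glen - ge + 1, glen - gs + 1, cstrand, w, w)
    expect_setequal(refl, got)
  }
})

test_that("systematic names follow the as-/nc-/int conventions with ordinals", {
  ann <- annotation(data.frame(
    name = c("psbK", "ndhD", "ndhDi", "rbcL", "accD"),
    start = c(100, 600, 700, 1200, 1700),
    stop = c(400, 1000, 800, 1500, 2000),
    strand = c("+", "+", "+", "-", "-"),
    kind = c("protein", "protein", "intron", "protein", "protein"),
    cluster_id = c(NA, NA, NA, "opB", "opB")), 2500)
  cand <- mk_cand(c(150, 620, 720, 890, 1550),
                  c(300, 640, 780, 960, 1650),
                  c("-", "-", "-", "-", "+"))
  cls <- classify_candidates(cand, ann, window_5p = 0, window_3p = 0)
  expect_equal(cls$name[1], "as-psbK")
  # two internal candidates antisense to ndhD get genomic-order ordinals
  expect_equal(cls$name[cls$start == 620], "as-ndhD-1")
  expect_equal(cls$name[cls$start == 890], "as-ndhD-2")
  # a candidate inside the intron span is named after the intron
  expect_equal(cls$name[cls$start == 720], "as-ndhDi")
  # intergenic between the two cluster genes
  expect_equal(cls$name[cls$start == 1550], "nc-rbcL-accDint")
})

test_that("terminus-window hits add a 5p/3p suffix to the name", {
  ann <- annotation(data.frame(name = "psaB", start = 500, stop = 900,
                               strand = "+", kind = "protein"), 1500)
  cls <- classify_candidates(mk_cand(c(480, 880), c(540, 950), c("-", "-")),
                             ann, window_5p = 10, window_3p = 10)
  expect_equal(cls$name, c("as-psaB-5p", "as-psaB-3p"))
})

test_that("category_summary counts antisense targets with unit fractions", {
  empty <- category_summary(
    classify_candidates(mk_cand(integer(), integer(), character()),
                        cluster_ann()))
  expect_equal(nrow(empty), 0L)
  ann <- annotation(data.frame(
    name = c("trnA", "trnB", "trnC", "ycf1"),
    start = c(100, 300, 500, 700), stop = c(180, 380, 580, 900),
    strand = "+", kind = c("tRNA", "tRNA", "tRNA", "protein")), 1000)
  cls <- classify_candidates(mk_cand(c(110, 310, 510, 720),
                                     c(170, 370, 570, 880),
                                     rep("-", 4)), ann)
  s <- category_summary(cls)
  expect_equal(s$count[s$category == "tRNA"], 3L)
  expect_equal(s$fraction[s$category == "ycf"], 0.25)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-12)
  # group-by oracle
  want <- table(cls$target_category[cls$ncrna_class == "antisense"])
  expect_equal(setNames(s$count, s$category), c(want)[s$category],
               ignore_attr = TRUE)
})
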