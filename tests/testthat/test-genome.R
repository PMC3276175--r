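test_that("plastome validates length, residues and inverted repeat", {
  p <- plastome(10, "ACGTACGTNN")
  expect_s3_class(p, "plastome")
  expect_error(plastome(9, "ACGTACGTNN"), "does not match")
  expect_error(plastome(4, "ACXT"), "A,C,G,T,N")
  expect_error(plastome(100, inverted_repeat = list(c(10, 50), c(40, 90))),
               "overlap")
  p <- plastome(100, inverted_repeat = list(c(10, 30), c(70, 90)))
  expect_equal(p$inverted_repeat[[2]], c(70L, 90L))
})

test_that("annotation sorts features and enforces bounds and vocabulary", {
  f <- data.frame(name = c("G2", "G1"), start = c(500, 100),
                  stop = c(800, 400), strand = "+", kind = "protein")
  ann <- annotation(f, 1000)
  expect_equal(ann$features$name, c("G1", "G2"))
  expect_equal(annotation(NULL, 1000)$features |> nrow(), 0L)
  expect_error(annotation(transform(f, stop = c(1200, 400)), 1000),
               "outside")
  expect_error(annotation(transform(f, kind = "promoter"), 1000), "kind")
  expect_error(annotation(transform(f, start = c(900, 100)), 1000),
               "start > stop")
})

test_that("gene_category resolves map, kind, then naming heuristic", {
  expect_equal(gene_category(c("trnH", "rrn16", "psbA", "rps16", "ycf1",
                               "accD")),
               c("tRNA", "rRNA", "photosynthesis", "gene_expression",
                 "ycf", "misc_protein"))
  # explicit map wins over the heuristic
  expect_equal(gene_category("psbA", category_map = c(psbA = "ycf")), "ycf")
  # numbered instances fall back to the base name in the map
  expect_equal(gene_category("ndhD-2", kind = "protein"), "photosynthesis")
  map <- load_category_map()
  expect_equal(unname(map["ycf9"]), "ycf")
  expect_equal(gene_category("orf31", category_map = map), "misc_protein")
})

test_that("features_overlapping matches spec examples", {
  ann <- annotation(data.frame(name = "G1", start = 100, stop = 400,
                               strand = "+", kind = "protein"), 1000)
  expect_equal(nrow(features_overlapping(ann, 500, 600, "both")), 0L)
  expect_equal(features_overlapping(ann, 150, 300, "opposite-of:-")$name,
               "G1")
  expect_equal(nrow(features_overlapping(ann, 150, 300, "opposite-of:+")),
               0L)
  expect_error(features_overlapping(ann, 300, 150), "start must be <=")
  expect_error(features_overlapping(ann, 0, 10), "outside")
})

test_that("features_overlapping equals the brute-force scan on random instances", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(100, 1)
    start <- sample(2000, n, replace = TRUE)
    f <- data.frame(name = sprintf("g%03d", seq_len(n)), start = start,
                    stop = pmin(2000, start + sample(0:300, n, TRUE)),
                    strand = sample(c("+", "-"), n, TRUE),
                    kind = "protein")
    ann <- annotation(f, 2000)
    modes <- list("both" = c("+", "-"), "same:+" = "+", "same:-" = "-",
                  "opposite-of:+" = "-", "opposite-of:-" = "+")
    for (q in 1:25) {
      qs <- sample(2000, 1); qe <- min(2000, qs + sample(0:400, 1))
      mode <- sample(names(modes), 1)
      got <- features_overlapping(ann, qs, qe, mode)
      want <- oracle_overlap(ann$features, qs, qe, modes[[mode]])
      expect_equal(got$name, want$name)
    }
  }
})

test_that("GFF3 round trip preserves coordinates, strands, names and kinds", {
  skip_if_not_installed("rtracklayer")
  f <- data.frame(name = c("psbA", "trnK", "rps16i", "rrn16"),
                  start = c(200, 1500, 2500, 4000),
                  stop = c(1000, 1580, 2800, 5400),
                  strand = c("+", "-", "+", "+"),
                  kind = c("protein", "tRNA", "intron", "rRNA"),
                  cluster_id = c("opA", NA, NA, NA))
  ann <- annotation(f, 6000)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  back <- load_annotation(path)
  expect_equal(back$genome_length, 6000L)
  expect_equal(back$features[, c("name", "start", "stop", "strand", "kind",
                                 "category", "cluster_id")],
               ann$features[, c("name", "start", "stop", "strand", "kind",
                                "category", "cluster_id")])
})

test_that("GFF3 loader reports malformed lines by number and maps fields", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 1000",
               "chr c gene 100 400 . + . ID=G1"), sep = "\n",
             con = path)
  # that wrote space-separated fields: malformed
  expect_error(load_annotation(path), "line 3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 1000",
               paste("chr", "c", "gene", "100", "400", ".", "+", ".",
                     "ID=G1", sep = "\t")), path)
  ann <- load_annotation(path)
  expect_equal(nrow(ann$features), 1L)
  expect_equal(ann$features$start, 100L)
  expect_equal(ann$features$stop, 400L)
  expect_equal(ann$features$strand, "+")
  # empty feature section
  writeLines(c("##gff-version 3", "##sequence-region chr 1 1000"), path)
  expect_equal(nrow(load_annotation(path)$features), 0L)
  # coordinate beyond declared length
  writeLines(c("##gff-version 3", "##sequence-region chr 1 300",
               paste("chr", "c", "gene", "100", "400", ".", "+", ".",
                     "ID=G1", sep = "\t")), path)
  expect_error(load_annotation(path), "beyond declared genome length")
})

test_that("FASTA reader builds a plastome", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy", "ACGTACGTAC", "GTACGTACGT"), path)
  p <- read_plastome_fasta(path)
  expect_equal(p$length, 20L)
  expect_equal(substr(p$residues, 1, 4), "ACGT")
})
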