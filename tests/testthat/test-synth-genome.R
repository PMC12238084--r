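chrom_df <- function(len = 50000, gc = 0.45, name = "chr1")
  data.frame(name = name, length = len, gc = gc, stringsAsFactors = FALSE)

test_that("identical seeds give byte-identical FASTA and truth", {
  plants <- list(plant_spec(strrep("ACGTT", 3), 60, 0.05, 0.01, "chr1"))
  g1 <- generate_genome(chrom_df(), plants, seed = 11)
  g2 <- generate_genome(chrom_df(), plants, seed = 11)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$truth, g2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_genome(chrom_df(), plants, seed = 12)
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("zero-divergence plants are exact monomer repetitions", {
  mono <- "GATTACACA"
  g <- generate_genome(chrom_df(), list(
    plant_spec(mono, 80, 0, 0, "chr1", position = 1000)), seed = 2)
  tr <- g$truth
  expect_equal(tr$start, 1000)
  expect_equal(tr$end, 1000 + 80 * nchar(mono))
  expect_equal(substr(g$sequences[["chr1"]], 1001, tr$end),
               strrep(mono, 80))
  expect_equal(tr$identity, 100)
})

test_that("realized identity tracks the divergence rate (binomial bound)", {
  # 10 kb of planted array at 5% substitution divergence
  g <- generate_genome(chrom_df(20000), list(
    plant_spec(strrep("ACGTTGCCTA", 10), 100, 0.05, 0, "chr1")), seed = 3)
  expect_lt(abs(g$truth$identity - 95), 1.5)
  # and the sequence itself differs from the perfect array accordingly
  tr <- g$truth
  planted <- substr(g$sequences[["chr1"]], tr$start + 1, tr$end)
  perfect <- strrep(strrep("ACGTTGCCTA", 10), 100)
  diffs <- sum(strsplit(planted, "")[[1]] != strsplit(perfect, "")[[1]])
  expect_lt(abs(100 * (1 - diffs / nchar(perfect)) - tr$identity), 0.06)
})

test_that("background GC is within 2% of the specification", {
  for (gc in c(0.35, 0.5, 0.65)) {
    g <- generate_genome(chrom_df(100000, gc), seed = 4)
    expect_lt(abs(oligo_gc(g$sequences[["chr1"]]) / 100 - gc), 0.02)
  }
})

test_that("impossible placements raise errors naming the plant", {
  expect_error(generate_genome(chrom_df(100), list(
    plant_spec("ACGTACGTAC", 50, 0, 0, "chr1")), seed = 1),
    "plant 1")
  expect_error(generate_genome(chrom_df(), list(
    plant_spec("ACGT", 10, 0, 0, "chrX")), seed = 1), "unknown")
  expect_error(generate_genome(chrom_df(), list(
    plant_spec("ACGT", 10, 0, 0, "chr1", position = 49990)), seed = 1),
    "out of range")
})

test_that("recovery evaluation handles exact, empty and shifted detections", {
  truth <- data.frame(chrom = "c1", start = c(0, 1000), end = c(500, 1500))
  exact <- data.frame(chrom = "c1", start = c(0, 1000), end = c(500, 1500))
  ev <- evaluate_recovery(truth, exact)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  empty <- exact[0, ]
  ev0 <- evaluate_recovery(truth, empty)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  expect_true(ev0$vacuous_precision)
  # 40% overlap at a 50% threshold is not recovered
  shifted <- data.frame(chrom = "c1", start = 300, end = 800)
  # overlap with truth1 = 200/500 = 0.4 both ways
  ev40 <- evaluate_recovery(truth[1, ], shifted)
  expect_equal(ev40$recall, 0)
  expect_equal(ev40$precision, 0)
  expect_equal(evaluate_recovery(truth[1, ], shifted,
                                 min_reciprocal_overlap = 0.4)$recall, 1)
})

test_that("each detected array consumes at most one truth record", {
  truth <- data.frame(chrom = "c1", start = c(0, 100), end = c(100, 200))
  # one detection spanning both truths at 50% reciprocal each
  det <- data.frame(chrom = "c1", start = 0, end = 200)
  ev <- evaluate_recovery(truth, det)
  expect_equal(ev$n_recovered, 1L)
  expect_equal(ev$recall, 0.5)
})
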