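# Detection, de-overlap and filter semantics.

make_arrays <- function(...) {
  rows <- list(...)
  at <- function(r, k, default) if (length(r) >= k) r[[k]] else default
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = r[[2]], end = r[[3]],
               period = at(r, 4, 10L), copy_number = at(r, 5, 50),
               pct_match = at(r, 6, 90), pct_indel = 0,
               score = at(r, 7, 100), consensus = strrep("A", 10),
               stringsAsFactors = FALSE)))
}

test_that("a planted perfect array is recovered with exact bounds", {
  set.seed(42)
  bg <- random_dna(10000)
  mono <- random_dna(20)
  g <- c(chr1 = paste0(substr(bg, 1, 4000), strrep(mono, 100),
                       substr(bg, 4001, 8000)))
  a <- detect_tandem_repeats(g)
  ov <- a[a$start < 6000 & a$end > 4000, ]
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$pct_match, 100)
  expect_equal(ov$start, 4000)
  expect_equal(ov$end, 6000)
  expect_equal(ov$period, 20L)
  expect_equal(ov$copy_number, 100)
  expect_true(ov$consensus %in% vapply(1:20, function(i)
    substr(strrep(mono, 2), i, i + 19), character(1)))
})

test_that("minimum score 50 is an inclusive threshold", {
  # 24-bp perfect period-4 array: score 48 < 50, not reported
  expect_equal(nrow(detect_tandem_repeats(c(c1 = strrep("ACGT", 6)))), 0L)
  # 25 bp: score 50, reported
  a <- detect_tandem_repeats(c(c1 = paste0(strrep("ACGT", 6), "A")))
  expect_equal(nrow(a), 1L)
  expect_equal(a$score, 50L)
  expect_equal(a$period, 4L)
})

test_that("all-N and too-short chromosomes give empty results with notices", {
  expect_equal(nrow(detect_tandem_repeats(c(cN = strrep("N", 500)))), 0L)
  expect_message(res <- detect_tandem_repeats(c(tiny = "ACGT")),
                 "skipping")
  expect_equal(nrow(res), 0L)
})

test_that("detection is deterministic and sorted by start", {
  set.seed(9)
  g <- c(chrA = paste0(random_dna(2000), strrep(random_dna(15), 60),
                       random_dna(2000), strrep(random_dna(8), 40),
                       random_dna(1000)))
  a1 <- detect_tandem_repeats(g)
  a2 <- detect_tandem_repeats(g)
  expect_identical(a1, a2)
  expect_true(all(diff(a1$start) >= 0))
  expect_true(all(a1$score >= 50))
})

test_that("resolve_overlaps keeps the best of overlapping pairs", {
  a <- make_arrays(list("chr1", 0, 100, 10, 10, 90, 90),
                   list("chr1", 50, 150, 10, 10, 90, 100))
  r <- resolve_overlaps(a)
  expect_equal(nrow(r), 1L)
  expect_equal(r$score, 100)
})

test_that("greedy pick removes both neighbours of a dominating array", {
  a <- make_arrays(list("chr1", 0, 100, 10, 10, 90, 90),
                   list("chr1", 50, 150, 10, 10, 90, 100),
                   list("chr1", 140, 240, 10, 10, 90, 90))
  r <- resolve_overlaps(a)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 50)
})

test_that("disjoint arrays and arrays on different chromosomes all survive", {
  a <- make_arrays(list("chr1", 0, 100), list("chr1", 200, 300),
                   list("chr2", 0, 100))
  expect_equal(nrow(resolve_overlaps(a)), 3L)
  expect_equal(nrow(resolve_overlaps(a[0, ])), 0L)
})

test_that("resolved intervals are always pairwise disjoint per chromosome", {
  set.seed(31)
  for (case in 1:25) {
    n <- sample(2:40, 1)
    start <- sample(0:500, n, replace = TRUE)
    a <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                    start = start, end = start + sample(10:200, n, TRUE),
                    period = 10L, copy_number = 50, pct_match = 90,
                    pct_indel = 0, score = sample(50:500, n, TRUE),
                    consensus = "A", stringsAsFactors = FALSE)
    r <- resolve_overlaps(a)
    for (ch in unique(r$chrom)) {
      rc <- r[r$chrom == ch, ]
      rc <- rc[order(rc$start), ]
      if (nrow(rc) > 1)
        expect_true(all(rc$start[-1] >= rc$end[-nrow(rc)]))
    }
    # every discarded array overlaps a kept one of >= score
    kept_key <- paste(r$chrom, r$start, r$end, r$score)
    for (i in seq_len(nrow(a))) {
      key <- paste(a$chrom[i], a$start[i], a$end[i], a$score[i])
      if (key %in% kept_key) next
      rc <- r[r$chrom == a$chrom[i], ]
      ov <- rc$start < a$end[i] & rc$end > a$start[i]
      expect_true(any(ov & rc$score >= a$score[i]))
    }
  }
})

test_that("filter boundaries: period >= 10, copies >= 50, pct_match > 70", {
  a <- make_arrays(
    list("c", 0, 500, 10L, 50.0, 70.0, 100),   # pct_match exactly 70: out
    list("c", 600, 1100, 9L, 100, 99, 100),    # period 9: out
    list("c", 1200, 1700, 10L, 50.0, 70.1, 100),  # boundary pass
    list("c", 1800, 2300, 10L, 49.9, 99, 100), # copies below: out
    list("c", 2400, 2900, 2000L, 50.0, 100, 100)) # in
  f <- filter_arrays(a)
  expect_equal(f$start, c(1200, 2400))
})

test_that("filter equals a brute-force predicate oracle and is idempotent", {
  set.seed(5)
  n <- 200
  a <- data.frame(chrom = "c", start = seq_len(n) * 1000,
                  end = seq_len(n) * 1000 + 500,
                  period = sample(c(1, 9, 10, 11, 500), n, TRUE),
                  copy_number = sample(c(1, 49.9, 50, 50.1, 300), n, TRUE),
                  pct_match = sample(c(0, 69.9, 70, 70.1, 100), n, TRUE),
                  pct_indel = 0, score = 100L, consensus = "A",
                  stringsAsFactors = FALSE)
  f <- filter_arrays(a)
  oracle <- a[a$period >= 10 & a$copy_number >= 50 & a$pct_match > 70, ]
  rownames(oracle) <- NULL
  expect_identical(f, oracle)
  expect_identical(filter_arrays(f), f)
  # commutes with concatenation
  h1 <- a[1:100, ]; h2 <- a[101:200, ]
  both <- rbind(filter_arrays(h1), filter_arrays(h2))
  rownames(both) <- NULL
  expect_identical(both, f)
})

test_that("consensus monomer is the column majority", {
  # 3 copies of ACGT with one substituted column copy
  seg <- paste0("ACGT", "ACGT", "ATGT")
  expect_equal(consensus_monomer(seg, 4), "ACGT")
  expect_equal(consensus_monomer(strrep("GATTACA", 5), 7), "GATTACA")
})
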