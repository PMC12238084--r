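test_that("a verbatim planted probe gives one forward hit at identity 100", {
  set.seed(12)
  probe <- random_dna(45)
  g <- c(chr1 = paste0(random_dna(500), probe, random_dna(500)))
  h <- scan_probe(g, probe, "P1")
  h <- h[h$identity == 100, ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 500L)
  expect_equal(h$strand, "+")
})

test_that("a reverse-complement plant is reported on the minus strand", {
  set.seed(13)
  probe <- random_dna(45)
  g <- c(chr1 = paste0(random_dna(300), revcomp(probe), random_dna(300)))
  h <- scan_probe(g, probe, "P1")
  h <- h[h$identity == 100, ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$start, 300L)
})

test_that("identity threshold is strict: 9 of 45 substitutions out, 8 in", {
  set.seed(14)
  probe <- random_dna(45)
  mutate_n <- function(s, k) {
    pos <- sample(45, k)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  site9 <- mutate_n(probe, 9)   # identity exactly 80.0
  site8 <- mutate_n(probe, 8)   # identity 82.2
  g <- c(chr1 = paste0(random_dna(200), site9, random_dna(200), site8,
                       random_dna(200)))
  h <- scan_probe(g, probe, "P1")
  expect_true(445 %in% h$start)       # the 8-substitution site
  expect_false(200 %in% h$start)      # the 9-substitution site
  expect_equal(h$identity[h$start == 445], round(100 * 37 / 45, 1))
})

test_that("scan equals the naive sliding-Hamming oracle on random genomes", {
  set.seed(15)
  for (case in 1:5) {
    probe <- random_dna(20)
    g <- c(c1 = random_dna(800), c2 = random_dna(400))
    # low threshold so the oracle produces hits to compare
    h <- scan_probe(g, probe, "P", map_params(min_identity = 55))
    o <- oracle_scan(g, probe, 55)
    expect_equal(nrow(h), nrow(o))
    if (nrow(h) > 0) {
      expect_equal(h$chrom, o$chrom)
      expect_equal(h$start, o$start)
      expect_equal(h$strand, o$strand)
    }
  }
})

test_that("exact-match scanning equals exact string search on both strands", {
  set.seed(16)
  probe <- random_dna(30)
  g <- c(c1 = paste0(random_dna(100), probe, random_dna(100), revcomp(probe),
                     random_dna(100)))
  h <- scan_probe(g, probe, "P", map_params(min_identity = 99))
  expect_equal(h$start, c(100L, 230L))
  expect_equal(h$strand, c("+", "-"))
})

test_that("probes with non-ACGT characters are rejected", {
  expect_error(scan_probe(c(c1 = "ACGTACGT"), "ACNT", "P"), "outside")
})

test_that("plasmid probes are fragmented, scanned and merged per site", {
  set.seed(18)
  long <- random_dna(3000)
  g <- c(c1 = paste0(random_dna(1000), long, random_dna(1000), long,
                     random_dna(500)))
  p <- map_params(probe_class = "plasmid")
  h <- scan_long_probe(g, long, "45S", p)
  plus <- h[h$strand == "+", ]
  expect_equal(nrow(plus), 2L)
  expect_true(all(plus$start == c(1000, 5000)))
  expect_true(all(plus$end == c(4000, 8000)))
  # absent probe
  h0 <- scan_long_probe(c(c1 = random_dna(2000)), random_dna(3000), "x", p)
  expect_equal(nrow(h0), 0L)
})

test_that("locus calling boundaries are strict (>30 hits; >1 hit/Mb)", {
  mkhits <- function(n, probe = "P")
    data.frame(chrom = "c1", start = seq(0, length.out = n, by = 100),
               end = seq(0, length.out = n, by = 100) + 45,
               strand = "+", identity = 100, probe_id = probe,
               stringsAsFactors = FALSE)
  lens <- c(c1 = 2e6)
  expect_equal(nrow(bin_and_call(mkhits(31), lens)), 1L)
  expect_equal(nrow(bin_and_call(mkhits(30), lens)), 0L)
  pl <- map_params(probe_class = "plasmid")
  expect_equal(nrow(bin_and_call(mkhits(2), lens, pl)), 1L)
  expect_equal(nrow(bin_and_call(mkhits(1), lens, pl)), 0L)
  expect_equal(nrow(bin_and_call(mkhits(31)[0, ], lens)), 0L)
})

test_that("adjacent called bins merge and counts are conserved", {
  h <- data.frame(chrom = "c1",
                  start = c(seq(0, by = 100, length.out = 40),
                            seq(1e6, by = 100, length.out = 40)),
                  strand = "+", identity = 100, probe_id = "P",
                  stringsAsFactors = FALSE)
  h$end <- h$start + 45
  loci <- bin_and_call(h, c(c1 = 5e6))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$count, 80L)
  expect_equal(loci$bin_start, 0)
  expect_equal(loci$bin_end, 2e6)
})

test_that("raising the count threshold never adds a locus", {
  set.seed(19)
  h <- data.frame(chrom = "c1", start = sample(0:3e6, 500),
                  strand = "+", identity = 100,
                  probe_id = sample(c("A", "B"), 500, TRUE),
                  stringsAsFactors = FALSE)
  h$end <- h$start + 45
  lens <- c(c1 = 4e6)
  n_prev <- Inf
  for (th in c(5, 30, 100)) {
    n <- nrow(bin_and_call(h, lens, map_params(count_threshold = th)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("hits beyond the declared chromosome length raise an error", {
  h <- data.frame(chrom = "c1", start = 999999, end = 1000044, strand = "+",
                  identity = 100, probe_id = "P", stringsAsFactors = FALSE)
  expect_error(bin_and_call(h, c(c1 = 5e5)), "beyond")
  expect_error(bin_and_call(h, c(c2 = 5e6)), "missing")
})

test_that("planting >30 probe targets inside one bin yields exactly one locus", {
  set.seed(20)
  probe <- random_dna(40)
  chunks <- c(random_dna(1000),
              rep(paste0(probe, random_dna(60)), 35),
              random_dna(1000))
  g <- c(c1 = paste(chunks, collapse = ""))
  h <- scan_probe(g, probe, "P1")
  loci <- bin_and_call(h, c(c1 = nchar(g[[1]])))
  expect_equal(nrow(loci), 1L)
  expect_gte(loci$count, 35L)
})
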