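test_that("tiling a 100-nt monomer at lengths 40-45 yields 600 candidates", {
  set.seed(3)
  mono <- random_dna(100)
  cand <- tile_candidates(mono, design_constraints())
  expect_equal(nrow(cand), 600L)
  expect_equal(length(unique(cand$start)), 100L)
  expect_setequal(unique(cand$length), 40:45)
})

test_that("short monomers are tandem-expanded and windows are substrings of the tandem", {
  mono <- "ACGTTGGCACGT"  # 12 nt
  cand <- tile_candidates(mono, design_constraints())
  expect_equal(nrow(cand), 12L * 6L)
  tandem <- strrep(mono, 10)
  for (s in cand$sequence)
    expect_true(grepl(s, tandem, fixed = TRUE))
})

test_that("invalid length range errors at construction", {
  expect_error(design_constraints(length_range = c(45, 40)), "min exceeds")
})

test_that("gc and tm annotations recompute exactly from the sequence", {
  set.seed(8)
  cand <- tile_candidates(random_dna(30), design_constraints())
  expect_equal(cand$gc, oligo_gc(cand$sequence))
  expect_equal(cand$tm, oligo_tm(cand$sequence))
  expect_equal(oligo_gc("GGCC"), 100)
  expect_equal(oligo_gc("AATT"), 0)
})

test_that("homopolymer candidates are rejected", {
  cand <- data.frame(cluster = "c1", start = 1L, length = 45L,
                     sequence = strrep("A", 45), stringsAsFactors = FALSE)
  cand$gc <- oligo_gc(cand$sequence)
  cand$tm <- oligo_tm(cand$sequence)
  expect_message(sel <- select_probes(cand), "no candidate")
  expect_equal(nrow(sel), 0L)
  expect_equal(attr(sel, "probeless"), "c1")
})

test_that("identical candidates yield exactly per_cluster_limit probes", {
  seqs <- rep("ACGTTGCATGCAACGGTTAACCGGATCGATCGTTAGCAATG", 10)
  cand <- data.frame(cluster = "c1", start = seq_along(seqs), length = 41L,
                     sequence = seqs, stringsAsFactors = FALSE)
  cand$gc <- oligo_gc(cand$sequence)
  cand$tm <- oligo_tm(cand$sequence)
  expect_equal(nrow(select_probes(cand)), 1L)
  expect_equal(nrow(select_probes(
    cand, design_constraints(per_cluster_limit = 3))), 3L)
})

test_that("selection equals a brute-force re-ranking oracle", {
  set.seed(17)
  mono <- random_dna(60)
  cons <- design_constraints(per_cluster_limit = 4)
  cand <- tile_candidates(mono, cons)
  sel <- select_probes(cand, cons)
  # oracle: independent predicate + ordering
  ok <- cand$gc >= 30 & cand$gc <= 70
  runmax <- vapply(cand$sequence, function(s)
    max(rle(strsplit(s, "")[[1]])$lengths), numeric(1))
  ok <- ok & runmax <= 6
  hp <- vapply(cand$sequence, function(s) {
    n <- nchar(s); stem <- 8; found <- FALSE
    for (i in 1:(n - stem + 1)) for (j in 1:(n - stem + 1)) {
      if (abs(i - j) < stem) next
      if (substr(s, j, j + stem - 1) ==
          revcomp(substr(s, i, i + stem - 1))) found <- TRUE
    }
    found
  }, logical(1))
  ok <- ok & !hp
  pool_med <- median(cand$tm)
  surv <- cand[ok, ]
  surv <- surv[order(abs(surv$tm - pool_med), surv$start, surv$length), ]
  expect_equal(sel$sequence, head(surv, 4)$sequence)
})

test_that("probe naming follows the chromosome/dispersal/telomere rules", {
  expect_equal(name_probe(c(chr8 = 90, chr2 = 10), 3), "C8-3")
  expect_equal(name_probe(NULL, 1, monomer = "TTTAGGG"), "Tel-1")
  expect_equal(name_probe(c(a = 20, b = 20, c = 20, d = 20, e = 20), 1),
               "Co-1")
  expect_equal(name_probe(NULL, 2), "U-2")
  expect_equal(name_probe(c(chr1 = 0, chr2 = 0), 1), "U-1")
  # rotations and reverse complement of the telomeric motif
  expect_true(is_telomeric("TAGGGTT"))
  expect_true(is_telomeric(revcomp("TTTAGGG")))
  expect_true(is_telomeric(strrep("TTTAGGG", 2)))
  expect_false(is_telomeric("TTTAGGC"))
})

test_that("assigned names are injective with per-prefix running indices", {
  hits <- list(c(chr8 = 100), c(chr8 = 90, chr1 = 10), c(chr2 = 60, chr3 = 40),
               NULL, c(a = 1, b = 1, c = 1, d = 1, e = 1))
  monos <- c("GATTACA", "GATTACA", "GATTACA", "TTTAGGG", "GATTACA")
  ids <- assign_probe_names(hits, monos)
  expect_equal(ids, c("C8-1", "C8-2", "C2-1", "Tel-1", "Co-1"))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("the published channel assignment yields a 7 + 4 cocktail pair", {
  panel <- c("C8-21", "C4-13", "C10-9", "Co-516", "C10-7", "C5-2", "Tel-1",
             "C1-1", "C1-12", "C10-10", "C5-14")
  probes <- data.frame(probe_id = panel, stringsAsFactors = FALSE)
  assignment <- data.frame(
    probe_id = panel,
    channel = c(rep("TAMRA", 7), rep("FAM", 4)),
    stringsAsFactors = FALSE)
  ck <- compose_cocktails(probes, assignment)
  expect_equal(sum(ck$cocktail == "Multiplex #1" & ck$channel == "TAMRA"), 7L)
  expect_equal(sum(ck$cocktail == "Multiplex #2" & ck$channel == "FAM"), 4L)
  expect_equal(ck$probe_id[ck$cocktail == "Multiplex #1"], panel[1:7])
})

test_that("cocktail composition rejects unknown and duplicated probes", {
  probes <- data.frame(probe_id = c("C1-1", "C2-1"))
  expect_error(compose_cocktails(
    probes, data.frame(probe_id = "C9-9", channel = "FAM")), "C9-9")
  expect_error(compose_cocktails(
    probes, data.frame(probe_id = c("C1-1", "C1-1"),
                       channel = c("FAM", "TAMRA"))), "more than one")
  expect_equal(nrow(compose_cocktails(
    probes, data.frame(probe_id = character(), channel = character()))), 0L)
})
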