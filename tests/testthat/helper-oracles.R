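# Independent oracles, implemented with different algorithms from the
# package code paths they check.

# Wraparound alignment score by fitting alignment against an explicitly
# repeated monomer text (vectorized row DP with a cummax trick for the
# within-row gap propagation). Free text start/end; the whole segment is
# consumed.
oracle_wraparound_score <- function(segment, monomer,
                                    match = 2, mismatch = 7, indel = 7) {
  s <- strsplit(segment, "", fixed = TRUE)[[1]]
  n <- length(s)
  p <- nchar(monomer)
  reps <- ceiling(n / p) + 3
  t <- strsplit(strrep(monomer, reps), "", fixed = TRUE)[[1]]
  m <- length(t)
  prev <- numeric(m + 1)  # row 0: alignment may start after any text column
  for (i in seq_len(n)) {
    sub <- ifelse(t == s[i] & s[i] != "N", match, -mismatch)
    diagv <- prev[1:m] + sub
    vertv <- prev[2:(m + 1)] - indel
    v <- pmax(diagv, vertv)
    w <- c(prev[1] - indel, v)
    cm <- cummax(w + indel * (0:m))
    prev <- pmax(w, cm - indel * (0:m))
  }
  as.integer(max(prev))
}

# Plain full-matrix Needleman-Wunsch (unit weights). The identity metric
# maximizes (score, matches) lexicographically; with unit weights every
# such optimal alignment has columns = 2 * matches - score, so identity is
# 100 * matches / (2 * matches - score). Implemented here by encoding the
# lexicographic pair as score * BIG + matches in one numeric matrix.
oracle_nw_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  BIG <- 4 * (n + m + 1)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- -(0:m) * BIG
  S[, 1] <- -(0:n) * BIG
  for (i in 1:n) for (j in 1:m) {
    hit <- av[i] == bv[j] && av[i] != "N"
    S[i + 1, j + 1] <- max(S[i, j] + (if (hit) BIG + 1 else -BIG),
                           S[i, j + 1] - BIG,
                           S[i + 1, j] - BIG)
  }
  enc <- S[n + 1, m + 1]
  score <- floor(enc / BIG)      # matches lives in [0, BIG)
  matches <- enc - score * BIG
  100 * matches / (2 * matches - score)
}

# Naive sliding-Hamming probe scan on both strands (character comparison,
# no Biostrings), strict identity threshold.
oracle_scan <- function(genome, probe, min_identity = 80) {
  L <- nchar(probe)
  out <- list()
  rc <- repeatprobe::revcomp(probe)
  for (chrom in names(genome)) {
    chars <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < L) next
    for (strand in c("+", "-")) {
      pv <- strsplit(if (strand == "+") probe else rc, "", fixed = TRUE)[[1]]
      for (s in 1:(n - L + 1)) {
        win <- chars[s:(s + L - 1)]
        matches <- sum(win == pv & win != "N")
        idn <- 100 * matches / L
        if (idn > min_identity)
          out[[length(out) + 1]] <- data.frame(
            chrom = chrom, start = s - 1L, strand = strand,
            identity = idn, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), identity = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# raw sample with exactly the requested mean and SD
exact_sample <- function(mean, sd, n) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
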