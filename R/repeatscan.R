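# Tandem repeat detection. A simplified, deterministic detector in the
# spirit of Tandem Repeats Finder: exact k-mer seeds paired with their
# nearest previous occurrence give (position, distance) votes; dense
# per-distance position clusters become candidate arrays; the fundamental
# period is chosen by divisor voting on the self-match fraction; boundaries
# are refined by phase extension; the consensus is the column-majority
# monomer; and every candidate is re-scored exactly with the wraparound DP.

.empty_arrays <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             period = integer(), copy_number = numeric(),
             pct_match = numeric(), pct_indel = numeric(),
             score = integer(), consensus = character(),
             stringsAsFactors = FALSE)
}

# integer codes of all k-mers (window start positions 1..n-k+1); windows
# containing N (or other non-ACGT) are NA
.kmer_codes <- function(chars, k) {
  b <- match(chars, DNA_BASES) - 1L
  n <- length(b)
  if (n < k) return(numeric(0))
  y <- stats::filter(as.numeric(b), 4^(0:(k - 1L)), sides = 1L)
  as.numeric(y[k:n])
}

# nearest-previous-occurrence seed distances, capped at max_period
.seed_distances <- function(codes, max_period) {
  idx <- which(!is.na(codes))
  if (length(idx) < 2L) return(NULL)
  o <- idx[order(codes[idx], idx)]
  same <- diff(codes[o]) == 0
  d <- diff(o)
  keep <- same & d >= 1L & d <= max_period
  if (!any(keep)) return(NULL)
  list(pos = o[-1L][keep], dist = d[keep])
}

# smallest divisor of d whose phase self-match fraction over [start, end]
# is both >= 0.6 and within 90% of the best divisor's fraction
.estimate_period <- function(chars, start, end, d) {
  divs <- which(d %% seq_len(d) == 0L)
  len <- end - start + 1L
  f <- vapply(divs, function(q) {
    if (len < 2L * q) return(-1)
    i <- start:(end - q)
    if (length(i) > 20000L) i <- i[seq(1L, length(i), length.out = 20000L)]
    mean(chars[i] == chars[i + q])
  }, numeric(1L))
  fb <- max(f)
  if (fb <= 0) return(d)
  ok <- divs[f >= pmax(0.6, 0.9 * fb)]
  if (length(ok) == 0L) d else ok[1L]
}

# extend boundaries outward while the periodic phase keeps matching
# (tolerating up to 2 consecutive failures), then trim edge bases that
# break phase so perfect arrays keep exact boundaries
.refine_bounds <- function(chars, start, end, p, n) {
  i <- start - 1L; fails <- 0L; last_ok <- start
  while (i >= 1L && fails < 2L) {
    if (chars[i] != "N" && chars[i] == chars[i + p]) {
      last_ok <- i; fails <- 0L
    } else fails <- fails + 1L
    i <- i - 1L
  }
  start <- last_ok
  i <- end + 1L; fails <- 0L; last_ok <- end
  while (i <= n && fails < 2L) {
    if (chars[i] != "N" && chars[i] == chars[i - p]) {
      last_ok <- i; fails <- 0L
    } else fails <- fails + 1L
    i <- i + 1L
  }
  end <- last_ok
  trims <- 0L
  while (start < end && trims < p &&
         (chars[start] == "N" || chars[start] != chars[min(start + p, end)])) {
    start <- start + 1L; trims <- trims + 1L
  }
  trims <- 0L
  while (end > start && trims < p &&
         (chars[end] == "N" || chars[end] != chars[max(end - p, start)])) {
    end <- end - 1L; trims <- trims + 1L
  }
  c(start, end)
}

#' Column-majority consensus monomer of a periodic segment
#'
#' Chops the segment into full period-length frames and takes the majority
#' base per column (ties broken alphabetically A < C < G < T; `N` is never
#' elected unless a column has no called base, in which case `A` is used).
#'
#' @param segment A/C/G/T/N string, at least one full period long.
#' @param period Monomer length in bp.
#' @return Consensus monomer string of length `period`.
#' @export
consensus_monomer <- function(segment, period) {
  .check_dna(segment, "segment")
  period <- as.integer(period)
  stopifnot(period >= 1L, nchar(segment) >= period)
  chars <- strsplit(segment, "", fixed = TRUE)[[1L]]
  ncopy <- length(chars) %/% period
  m <- matrix(chars[seq_len(ncopy * period)], nrow = period)
  counts <- vapply(DNA_BASES, function(b) rowSums(m == b), numeric(period))
  if (period == 1L) counts <- matrix(counts, nrow = 1L,
                                     dimnames = list(NULL, DNA_BASES))
  pick <- max.col(counts, ties.method = "first")
  none <- rowSums(counts) == 0
  pick[none] <- 1L
  paste(DNA_BASES[pick], collapse = "")
}

#' Detect tandem repeat arrays in a genome
#'
#' Scans each chromosome for tandem repeat arrays and reports, per array,
#' its 0-based half-open coordinates, period, copy number (span / period,
#' one decimal), percent matching and indel alignment columns against the
#' column-majority consensus, the exact wraparound alignment score under
#' `params$weights`, and the consensus monomer. Only arrays with
#' `score >= min_score` (inclusive) and `period <= max_period` are
#' reported; arrays with more than 20% `N` content are dropped. Within a
#' chromosome arrays are sorted by start; detection is deterministic.
#'
#' Chromosomes too short to seed (shorter than twice the effective seed
#' k-mer, which shrinks to `floor(length/2)` on short sequences) are
#' skipped with a notice.
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param params [detection_params()].
#' @return A data frame of arrays (class `tandem_repeat_arrays` columns:
#'   `chrom, start, end, period, copy_number, pct_match, pct_indel, score,
#'   consensus`).
#' @export
#' @examples
#' g <- c(chrA = strrep("ACGTT", 30))
#' detect_tandem_repeats(g)
detect_tandem_repeats <- function(genome, params = detection_params()) {
  genome <- .as_genome(genome)
  stopifnot(inherits(params, "detection_params"))
  out <- lapply(names(genome), function(chrom)
    .detect_one(genome[[chrom]], chrom, params))
  res <- do.call(rbind, c(list(.empty_arrays()), out))
  rownames(res) <- NULL
  res
}

.detect_one <- function(seq, chrom, params) {
  n <- nchar(seq)
  k <- min(params$seed_kmer, max(3L, n %/% 2L))
  if (n < 2L * k) {
    message("skipping ", chrom, ": length ", n,
            " is shorter than twice the seed k-mer (", k, ")")
    return(.empty_arrays())
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- .kmer_codes(chars, k)
  seeds <- .seed_distances(codes, params$max_period)
  if (is.null(seeds)) return(.empty_arrays())

  cands <- list()
  for (d in sort(unique(seeds$dist))) {
    ps <- sort(seeds$pos[seeds$dist == d])
    tol <- max(4L * d, 300L)
    grp <- cumsum(c(1L, diff(ps) > tol))
    for (g in split(ps, grp)) {
      if (length(g) < 2L) next
      start <- max(1L, min(g) - d)
      end <- min(n, max(g) + k - 1L)
      p <- .estimate_period(chars, start, end, d)
      if (end - start + 1L < 2L * p) next
      b <- .refine_bounds(chars, start, end, p, n)
      cands[[length(cands) + 1L]] <- c(b[1L], b[2L], p)
    }
  }
  if (length(cands) == 0L) return(.empty_arrays())
  cm <- unique(do.call(rbind, cands))
  cm <- cm[order(cm[, 1L], cm[, 2L], cm[, 3L]), , drop = FALSE]

  rows <- vector("list", nrow(cm))
  for (r in seq_len(nrow(cm))) {
    s <- cm[r, 1L]; e <- cm[r, 2L]; p <- cm[r, 3L]
    len <- e - s + 1L
    if (len < p || p > params$max_period) next
    seg_chars <- chars[s:e]
    if (mean(seg_chars == "N") > 0.2) next
    segment <- paste(seg_chars, collapse = "")
    cons <- consensus_monomer(segment, p)
    aln <- wraparound_align(segment, cons, params$weights)
    if (aln$score < params$min_score) next
    cols <- aln$matches + aln$mismatches + aln$indels
    rows[[r]] <- data.frame(
      chrom = chrom, start = s - 1L, end = e,
      period = as.integer(p),
      copy_number = .round_half_up(len / p, 1L),
      pct_match = .round_half_up(100 * aln$matches / cols, 1L),
      pct_indel = .round_half_up(100 * aln$indels / cols, 1L),
      score = as.integer(aln$score), consensus = cons,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(list(.empty_arrays()), rows))
  res <- unique(res)
  res[order(res$start, res$end, res$period), , drop = FALSE]
}

#' Remove overlapping arrays, keeping the best
#'
#' Greedy best-first interval selection: arrays are visited by descending
#' score (ties: longer span, then smaller start, then input order) and an
#' array is retained iff it does not overlap an already-retained array on
#' the same chromosome. Every discarded array therefore overlaps a retained
#' array of greater-or-equal score, and retained intervals are pairwise
#' disjoint per chromosome.
#'
#' @param arrays Array data frame as from [detect_tandem_repeats()].
#' @return The retained subset, ordered by chromosome (input order) then
#'   start.
#' @export
resolve_overlaps <- function(arrays) {
  if (nrow(arrays) == 0L) return(arrays)
  n <- nrow(arrays)
  ord <- order(-arrays$score, -(arrays$end - arrays$start),
               arrays$start, seq_len(n))
  keep <- logical(n)
  kept <- list()
  for (i in ord) {
    ch <- arrays$chrom[i]
    iv <- kept[[ch]]
    s <- arrays$start[i]; e <- arrays$end[i]
    if (is.null(iv) || !any(s < iv[, 2L] & e > iv[, 1L])) {
      keep[i] <- TRUE
      kept[[ch]] <- rbind(iv, c(s, e))
    }
  }
  res <- arrays[keep, , drop = FALSE]
  chrom_order <- match(res$chrom, unique(arrays$chrom))
  res <- res[order(chrom_order, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter arrays on period, copy number and percent match
#'
#' Pure subset filter: retained iff `period >= min_period` AND
#' `copy_number >= min_copies` AND `pct_match > min_pct_match` (strict).
#' Order is preserved; the filter is idempotent.
#'
#' @param arrays Array data frame.
#' @param params [filter_params()].
#' @return The retained subset in input order.
#' @export
filter_arrays <- function(arrays, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  if (nrow(arrays) == 0L) return(arrays)
  keep <- arrays$period >= params$min_period &
    arrays$copy_number >= params$min_copies &
    arrays$pct_match > params$min_pct_match
  res <- arrays[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
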