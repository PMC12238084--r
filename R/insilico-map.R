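# Electronic localization: ungapped sliding-identity probe scanning on both
# strands (Biostrings does the window matching), fixed-bin locus calling
# with the published strict thresholds (>80% identity; >30 matches per bin
# for oligos, >1 match/Mb for plasmid-scale probes), and idiogram rendering.

.empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), identity = numeric(),
             probe_id = character(), stringsAsFactors = FALSE)
}

# largest mismatch count whose identity is still strictly above min_identity
.max_mismatches <- function(L, min_identity) {
  m <- floor(L * (1 - min_identity / 100) - 1e-9)
  max(as.integer(m), -1L)
}

#' Scan a genome for windows matching an oligo probe
#'
#' Reports every window of probe length, on both strands, whose ungapped
#' identity (100 x matching positions / probe length, Hamming model) is
#' strictly greater than `params$min_identity`. Hit coordinates are 0-based
#' window starts on the forward strand; hits are sorted by chromosome
#' (genome order), position, then strand. `N` bases in the genome never
#' match. Chromosomes shorter than the probe are skipped with a notice.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param probe Probe sequence (A/C/G/T only).
#' @param probe_id Probe name used in the output.
#' @param params [map_params()].
#' @return Data frame `chrom, start, end, strand, identity, probe_id`.
#' @export
scan_probe <- function(genome, probe, probe_id = "probe",
                       params = map_params()) {
  genome <- .as_genome(genome)
  .check_dna(probe, "probe", allow_n = FALSE)
  stopifnot(inherits(params, "map_params"))
  L <- nchar(probe)
  mmax <- .max_mismatches(L, params$min_identity)
  if (mmax < 0L) return(.empty_hits())
  pat_fwd <- Biostrings::DNAString(probe)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  rows <- list()
  for (chrom in names(genome)) {
    if (nchar(genome[[chrom]]) < L) {
      message("skipping ", chrom, ": shorter than probe ", probe_id)
      next
    }
    subject <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_fwd else pat_rev
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = mmax,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m)
      mm <- Biostrings::neditStartingAt(pat, subject, starting.at = starts,
                                        with.indels = FALSE, fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = starts - 1L, end = starts - 1L + L,
        strand = strand,
        identity = .round_half_up(100 * (L - mm) / L, 1L),
        probe_id = probe_id, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(list(.empty_hits()), rows))
  res <- res[order(match(res$chrom, names(genome)), res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a genome with a plasmid-scale probe by windowed fragmentation
#'
#' The long sequence is cut into `plasmid_window`-length fragments at
#' `plasmid_step` intervals (plus a final fragment flush with the end);
#' each fragment is scanned as an oligo, and overlapping hits from adjacent
#' fragments are merged into one region per site (per chromosome and
#' strand), keeping the maximum fragment identity and the fragment count.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param long_sequence Probe sequence at least `plasmid_window` long.
#' @param probe_id Probe name used in the output.
#' @param params [map_params()] with `probe_class = "plasmid"`.
#' @return Data frame `chrom, start, end, strand, identity, probe_id,
#'   n_fragments` with merged 0-based half-open regions.
#' @export
scan_long_probe <- function(genome, long_sequence, probe_id = "plasmid",
                            params = map_params(probe_class = "plasmid")) {
  stopifnot(inherits(params, "map_params"))
  if (params$probe_class != "plasmid")
    stop("scan_long_probe requires probe_class = \"plasmid\"", call. = FALSE)
  .check_dna(long_sequence, "long_sequence", allow_n = FALSE)
  n <- nchar(long_sequence)
  w <- params$plasmid_window
  if (n < w)
    stop("long_sequence is shorter than plasmid_window", call. = FALSE)
  starts <- seq(1L, n - w + 1L, by = params$plasmid_step)
  if (starts[length(starts)] != n - w + 1L) starts <- c(starts, n - w + 1L)
  frags <- substring(long_sequence, starts, starts + w - 1L)
  hits <- lapply(seq_along(frags), function(i)
    scan_probe(genome, frags[i], probe_id = probe_id, params = params))
  hits <- do.call(rbind, hits)
  if (nrow(hits) == 0L) {
    out <- .empty_hits()
    out$n_fragments <- integer(0)
    return(out)
  }
  out <- list()
  for (chrom in unique(hits$chrom)) for (strand in c("+", "-")) {
    h <- hits[hits$chrom == chrom & hits$strand == strand, , drop = FALSE]
    if (nrow(h) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(start = h$start + 1L, end = h$end))
    for (k in seq_along(ir)) {
      s <- BiocGenerics::start(ir)[k] - 1L
      e <- BiocGenerics::end(ir)[k]
      inr <- h$start >= s & h$end <= e
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e, strand = strand,
        identity = max(h$identity[inr]), probe_id = probe_id,
        n_fragments = sum(inr), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bin probe hits and call loci
#'
#' Hits are assigned to fixed non-overlapping bins of `bin_size` bp
#' anchored at coordinate 0. Under the oligo rule a bin is called when its
#' hit count is strictly greater than `count_threshold` (">30 matches");
#' under the plasmid rule when hits per Mb of bin span is strictly greater
#' than `density_threshold` ("> 1 match per megabase"; the last bin of a
#' chromosome is pro-rated to its actual span). Adjacent called bins for
#' the same probe are merged into one locus with the summed count.
#'
#' @param hits Hit data frame from [scan_probe()] / [scan_long_probe()].
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param params [map_params()]; `probe_class` picks the rule.
#' @return Data frame `chrom, bin_start, bin_end, count, probe_id, rule`
#'   with 0-based half-open locus coordinates.
#' @export
bin_and_call <- function(hits, chrom_lengths, params = map_params()) {
  stopifnot(inherits(params, "map_params"))
  empty <- data.frame(chrom = character(), bin_start = numeric(),
                      bin_end = numeric(), count = integer(),
                      probe_id = character(), rule = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  unknown <- setdiff(hits$chrom, names(chrom_lengths))
  if (length(unknown) > 0L)
    stop("hits on chromosome(s) missing from chrom_lengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(hits$start >= chrom_lengths[hits$chrom] | hits$start < 0))
    stop("hit position beyond declared chromosome length", call. = FALSE)
  rule <- if (params$probe_class == "oligo") "count" else "density"
  bs <- params$bin_size
  out <- list()
  for (pid in unique(hits$probe_id)) {
    hp <- hits[hits$probe_id == pid, , drop = FALSE]
    for (chrom in unique(hp$chrom)) {
      h <- hp[hp$chrom == chrom, , drop = FALSE]
      bin <- h$start %/% bs
      tab <- table(bin)
      bins <- as.numeric(names(tab))
      counts <- as.integer(tab)
      span <- pmin(bs, chrom_lengths[[chrom]] - bins * bs)
      called <- if (rule == "count") counts > params$count_threshold
                else counts / (span / 1e6) > params$density_threshold
      if (!any(called)) next
      bins <- bins[called]; counts <- counts[called]
      grp <- cumsum(c(1L, diff(bins) > 1))
      for (g in unique(grp)) {
        bsel <- bins[grp == g]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, bin_start = min(bsel) * bs,
          bin_end = min((max(bsel) + 1) * bs, chrom_lengths[[chrom]]),
          count = sum(counts[grp == g]), probe_id = pid, rule = rule,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, c(list(empty), out))
  res <- res[order(match(res$chrom, names(chrom_lengths)), res$bin_start,
                   res$probe_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
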