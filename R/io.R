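# File-format edges: FASTA via Biostrings (gzip-transparent), TRF-.dat-like
# array TSV, BED6, probe FASTA/TSV.

#' Read a genome FASTA
#'
#' @param path FASTA path (gzip transparent).
#' @return Named uppercase character vector; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' For a [generate_genome()] result the generation seed is recorded in each
#' header description for provenance.
#'
#' @param x Named character vector of sequences, or a `synthetic_genome`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(x, path) {
  if (inherits(x, "synthetic_genome")) {
    seqs <- x$sequences
    names(seqs) <- sprintf("%s seed=%d synthetic", names(seqs), x$seed)
  } else seqs <- x
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a truth BED6 of planted arrays
#'
#' @param truth Truth data frame from [generate_genome()].
#' @param path Output BED path.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(truth$chrom, truth$start, truth$end,
                    sprintf("%s|p%d|c%d", truth$name, truth$period,
                            truth$copies),
                    0L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read tandem repeat arrays as TRF-.dat-like TSV
#'
#' Columns: `chrom, start, end, period, copy_number, pct_match, pct_indel,
#' score, consensus` (0-based half-open coordinates).
#'
#' @param arrays Array data frame.
#' @param path TSV path.
#' @return `read_arrays_tsv` returns the array data frame.
#' @export
write_arrays_tsv <- function(arrays, path) {
  utils::write.table(arrays, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_arrays_tsv
#' @export
read_arrays_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character",
                                   consensus = "character"))
}

#' Write arrays as BED6
#'
#' Name is a running array id; the BED score column is the alignment score
#' capped at 1000.
#'
#' @param arrays Array data frame.
#' @param path Output BED path.
#' @export
write_arrays_bed <- function(arrays, path) {
  n <- nrow(arrays)
  bed <- data.frame(arrays$chrom, arrays$start, arrays$end,
                    sprintf("TR%04d", seq_len(max(n, 0L))),
                    pmin(arrays$score, 1000L), "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a probe table as FASTA
#'
#' Headers carry the probe id plus cluster, GC, Tm and channel annotations.
#'
#' @param probes Probe data frame with `probe_id, sequence, cluster, gc,
#'   tm` and optionally `channel`.
#' @param path Output FASTA path.
#' @export
write_probe_fasta <- function(probes, path) {
  channel <- if ("channel" %in% names(probes)) probes$channel
             else rep("unassigned", nrow(probes))
  seqs <- probes$sequence
  names(seqs) <- sprintf("%s cluster=%s gc=%.1f tm=%.1f channel=%s",
                         probes$probe_id, probes$cluster, probes$gc,
                         probes$tm, channel)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write called loci as BED6
#'
#' Name is the probe id; the score column is the hit count capped at 1000.
#'
#' @param loci Locus data frame from [bin_and_call()].
#' @param path Output BED path.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$bin_start, loci$bin_end,
                    loci$probe_id, pmin(loci$count, 1000L), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
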