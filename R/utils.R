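# Shared sequence helpers. Sequences travel as uppercase character strings
# (A/C/G/T/N); Biostrings objects are used at the I/O and scanning edges.

DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty character string", call. = FALSE)
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alpha), x))
    stop(what, " contains characters outside ", alpha, call. = FALSE)
  invisible(x)
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TTTAGGG")
revcomp <- function(x) .revcomp(toupper(x))

# round half away from zero (TRF .dat / printed-table convention; base R
# round() uses banker's rounding which would give 41.0 vs 41.05 -> 41.0 but
# 0.5-at-digit cases like 49.95 -> 49.9)
.round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# coerce genome input (named character vector, DNAStringSet, or FASTA path)
# to a named uppercase character vector
.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- toupper(as.character(genome))
    names(seqs) <- sub("\\s.*$", "", names(genome))
    return(seqs)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    return(read_genome_fasta(genome))
  }
  if (!is.character(genome) || length(genome) == 0L)
    stop("genome must be a named character vector, DNAStringSet or FASTA path",
         call. = FALSE)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  toupper(genome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
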