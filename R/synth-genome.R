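# Seeded synthetic chromosomes with planted tandem repeat arrays and a
# truth table, standing in for a multi-gigabase assembly at desk scale.
# One seeded pseudo-random stream drives the whole generation, so identical
# seeds give byte-identical FASTA/BED outputs.

#' Specification of one planted tandem repeat array
#'
#' @param monomer Monomer sequence (A/C/G/T).
#' @param copies Number of head-to-tail copies (>= 1).
#' @param divergence Per-base substitution probability in `[0, 0.5]`.
#' @param indel_rate Per-base insertion/deletion probability in `[0, 0.5]`
#'   (events are 1 bp; insertions copy a random base; indels are applied
#'   after substitutions so truth intervals stay exact).
#' @param chrom Target chromosome name.
#' @param position 0-based start position, or `"random"`.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(monomer, copies, divergence = 0, indel_rate = 0,
                       chrom, position = "random") {
  .check_dna(monomer, "monomer", allow_n = FALSE)
  stopifnot(copies >= 1, divergence >= 0, divergence <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5)
  structure(list(monomer = toupper(monomer), copies = as.integer(copies),
                 divergence = divergence, indel_rate = indel_rate,
                 chrom = chrom, position = position),
            class = "plant_spec")
}

.mutate_plant <- function(perfect, divergence, indel_rate) {
  chars <- strsplit(perfect, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  mutated <- 0L
  if (divergence > 0) {
    sub <- which(stats::runif(n) < divergence)
    if (length(sub) > 0L) {
      repl <- vapply(chars[sub], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1L))
      chars[sub] <- repl
      mutated <- mutated + length(sub)
    }
  }
  if (indel_rate > 0) {
    ev <- stats::runif(n)
    dels <- ev < indel_rate / 2
    ins <- ev >= indel_rate / 2 & ev < indel_rate
    out <- vector("list", n)
    for (i in seq_len(n)) {
      if (dels[i]) {
        out[[i]] <- character(0)
      } else if (ins[i]) {
        out[[i]] <- c(chars[i], sample(DNA_BASES, 1L))
      } else out[[i]] <- chars[i]
    }
    mutated <- mutated + sum(dels) + sum(ins)
    chars <- unlist(out)
  }
  list(seq = paste(chars, collapse = ""),
       identity = .round_half_up(100 * (n - mutated) / n, 1L))
}

#' Generate a synthetic genome with planted tandem repeat arrays
#'
#' Background bases are drawn i.i.d. at each chromosome's GC content; each
#' plant is its monomer repeated `copies` times with per-base substitutions
#' and 1-bp indels applied, overwritten onto the background at the
#' requested (or randomly drawn, non-overlapping with a 500 bp margin)
#' position. Identical seeds give byte-identical outputs. The truth table
#' records every plant's realized interval and identity.
#'
#' @param chroms Data frame with columns `name, length, gc` (GC as a
#'   fraction), or a list coercible to one.
#' @param plants List of [plant_spec()] objects (possibly empty).
#' @param seed Integer seed for the single generation stream.
#' @param max_attempts Placement retries per random plant before erroring.
#' @return A list of class `synthetic_genome`: `sequences` (named character
#'   vector), `truth` (data frame `chrom, start, end, name, period, copies,
#'   identity` with 0-based half-open coordinates) and `seed`.
#' @export
#' @examples
#' g <- generate_genome(data.frame(name = "chr1", length = 10000, gc = 0.4),
#'                      list(plant_spec(strrep("ACGTT", 4), 100,
#'                                      chrom = "chr1")), seed = 1)
#' g$truth
generate_genome <- function(chroms, plants = list(), seed = 1,
                            max_attempts = 200L) {
  chroms <- as.data.frame(chroms, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "length", "gc") %in% names(chroms)),
            all(chroms$length >= 1), all(chroms$gc >= 0 & chroms$gc <= 1))
  for (p in plants) stopifnot(inherits(p, "plant_spec"))
  set.seed(as.integer(seed))

  seqs <- character(nrow(chroms))
  names(seqs) <- chroms$name
  chars_by_chrom <- list()
  for (i in seq_len(nrow(chroms))) {
    gc <- chroms$gc[i]
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    chars_by_chrom[[chroms$name[i]]] <-
      sample(DNA_BASES, chroms$length[i], replace = TRUE, prob = prob)
  }

  truth <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      period = integer(), copies = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  occupied <- list()  # per chrom: matrix of [start, end) with margin
  margin <- 500
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    if (!p$chrom %in% chroms$name)
      stop("plant ", pi, ": unknown chromosome ", p$chrom, call. = FALSE)
    mut <- .mutate_plant(strrep(p$monomer, p$copies), p$divergence,
                         p$indel_rate)
    plen <- nchar(mut$seq)
    clen <- chroms$length[chroms$name == p$chrom]
    if (plen > clen)
      stop("plant ", pi, " does not fit on ", p$chrom, call. = FALSE)
    occ <- occupied[[p$chrom]]
    if (identical(p$position, "random")) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        s <- sample.int(clen - plen + 1L, 1L) - 1L  # 0-based
        if (is.null(occ) ||
            !any(s - margin < occ[, 2L] & s + plen + margin > occ[, 1L])) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place plant ", pi, " on ", p$chrom, " after ",
             max_attempts, " attempts", call. = FALSE)
    } else {
      s <- as.numeric(p$position)
      if (s < 0 || s + plen > clen)
        stop("plant ", pi, ": fixed position out of range", call. = FALSE)
      if (!is.null(occ) && any(s < occ[, 2L] & s + plen > occ[, 1L]))
        stop("plant ", pi, ": fixed position overlaps another plant",
             call. = FALSE)
    }
    occupied[[p$chrom]] <- rbind(occ, c(s, s + plen))
    chars_by_chrom[[p$chrom]][(s + 1L):(s + plen)] <-
      strsplit(mut$seq, "", fixed = TRUE)[[1L]]
    truth <- rbind(truth, data.frame(
      chrom = p$chrom, start = s, end = s + plen,
      name = sprintf("plant%d", pi), period = nchar(p$monomer),
      copies = p$copies, identity = mut$identity,
      stringsAsFactors = FALSE))
  }
  for (nm in names(seqs)) seqs[[nm]] <- paste(chars_by_chrom[[nm]],
                                              collapse = "")
  structure(list(sequences = seqs, truth = truth, seed = as.integer(seed)),
            class = "synthetic_genome")
}

#' Evaluate detector recovery against planted truth
#'
#' A truth record is recovered iff some detected array reciprocally
#' overlaps it by at least `min_reciprocal_overlap` (intersection over
#' each interval's own length); each detected array consumes at most one
#' truth record (greedy, by descending overlap). Recall is recovered
#' truths over all truths. Precision is the fraction of detected arrays
#' that reciprocally overlap at least one truth. Empty detection reports
#' precision 1 with `vacuous_precision = TRUE`.
#'
#' @param truth Truth data frame (`chrom, start, end`, 0-based half-open).
#' @param detected Detected array data frame (`chrom, start, end`).
#' @param min_reciprocal_overlap Reciprocal-overlap fraction (default 0.5).
#' @return A list: `recall`, `precision`, `n_truth`, `n_detected`,
#'   `n_recovered`, `vacuous_precision`.
#' @export
evaluate_recovery <- function(truth, detected, min_reciprocal_overlap = 0.5) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nd == 0L)
    return(list(recall = if (nt == 0L) 1 else 0, precision = 1,
                n_truth = nt, n_detected = 0L, n_recovered = 0L,
                vacuous_precision = TRUE))
  pairs <- list()
  det_matches <- logical(nd)
  for (ti in seq_len(nt)) for (di in seq_len(nd)) {
    if (truth$chrom[ti] != detected$chrom[di]) next
    ov <- min(truth$end[ti], detected$end[di]) -
      max(truth$start[ti], detected$start[di])
    if (ov <= 0) next
    rt <- ov / (truth$end[ti] - truth$start[ti])
    rd <- ov / (detected$end[di] - detected$start[di])
    if (rt >= min_reciprocal_overlap && rd >= min_reciprocal_overlap) {
      det_matches[di] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(ti, di, min(rt, rd))
    }
  }
  recovered <- logical(nt)
  if (length(pairs) > 0L) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, 3L], pm[, 1L], pm[, 2L]), , drop = FALSE]
    det_used <- logical(nd)
    for (r in seq_len(nrow(pm))) {
      ti <- pm[r, 1L]; di <- pm[r, 2L]
      if (!recovered[ti] && !det_used[di]) {
        recovered[ti] <- TRUE
        det_used[di] <- TRUE
      }
    }
  }
  list(recall = if (nt == 0L) 1 else sum(recovered) / nt,
       precision = sum(det_matches) / nd,
       n_truth = nt, n_detected = nd, n_recovered = sum(recovered),
       vacuous_precision = FALSE)
}
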