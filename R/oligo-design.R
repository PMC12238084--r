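# Oligo probe design from cluster representatives: cyclic window tiling over
# the tandem context, composition screens (GC, homopolymer, hairpin stem),
# melting-temperature ranking, probe naming, and fluorophore cocktails.

#' GC content of oligo sequences
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return GC percent per sequence.
#' @export
oligo_gc <- function(x) {
  x <- toupper(x)
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    100 * sum(b %in% c("G", "C")) / length(b)
  }, numeric(1L), USE.NAMES = FALSE)
}

# nearest-neighbor duplex parameters (unified NN set: dH kcal/mol,
# dS cal/mol/K), with terminal initiation terms and a sodium entropy
# correction; only the relative ranking matters for probe selection
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature of oligo sequences
#'
#' Unified nearest-neighbor thermodynamics with terminal initiation terms,
#' a monovalent-salt entropy correction (`0.368 * (len - 1) * ln[Na+]`) and
#' `Tm = 1000 * dH / (dS + R * ln(C/4)) - 273.15`. Defaults: 50 mM Na+,
#' 200 nM oligo. Probe selection only uses Tm for relative ranking.
#'
#' @param x Character vector of A/C/G/T sequences (length >= 2 nt).
#' @param na_conc Monovalent cation concentration, mol/L.
#' @param oligo_conc Oligo concentration, mol/L.
#' @return Melting temperature estimate per sequence, degrees Celsius.
#' @export
oligo_tm <- function(x, na_conc = 0.05, oligo_conc = 2e-7) {
  x <- toupper(x)
  vapply(x, function(s) {
    n <- nchar(s)
    if (n < 2L) return(NA_real_)
    steps <- substring(s, 1:(n - 1L), 2:n)
    dh <- sum(.NN_DH[steps])
    ds <- sum(.NN_DS[steps])
    for (term in c(substr(s, 1L, 1L), substr(s, n, n))) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1L) * log(na_conc)
    1000 * dh / (ds + 1.987 * log(oligo_conc / 4)) - 273.15
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Tile candidate oligo windows over a monomer in tandem context
#'
#' Enumerates all windows of each allowed length, stepped by 1 nt, over the
#' monomer concatenated with itself (windows may span the monomer
#' junction): for each length there is one window per monomer phase, so a
#' monomer of period p yields `p * number_of_lengths` candidates. Monomers
#' shorter than the minimum length are tandem-expanded, so every candidate
#' is by construction a substring of a real tandem array of the monomer.
#'
#' @param representative Monomer sequence (A/C/G/T).
#' @param constraints [design_constraints()].
#' @param cluster Cluster id to annotate candidates with.
#' @return Data frame `cluster, start` (1-based phase in the monomer),
#'   `length, sequence, gc, tm`.
#' @export
#' @examples
#' nrow(tile_candidates(strrep("ACGTT", 20), design_constraints()))  # 600
tile_candidates <- function(representative, constraints = design_constraints(),
                            cluster = "cluster1") {
  .check_dna(representative, "representative", allow_n = FALSE)
  stopifnot(inherits(constraints, "design_constraints"))
  p <- nchar(representative)
  lmin <- constraints$length_range[1L]
  lmax <- constraints$length_range[2L]
  reps <- ceiling(lmax / p) + 1L
  ext <- strrep(representative, reps)
  rows <- list()
  for (L in lmin:lmax) {
    starts <- seq_len(p)
    seqs <- substring(ext, starts, starts + L - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cluster, start = starts, length = L, sequence = seqs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$length), , drop = FALSE]
  out$gc <- oligo_gc(out$sequence)
  out$tm <- oligo_tm(out$sequence)
  rownames(out) <- NULL
  out
}

.max_homopolymer <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

# TRUE if s contains a window of length `stem` whose reverse complement
# also occurs at a disjoint position (a self-complementary stem)
.has_hairpin <- function(s, stem) {
  n <- nchar(s)
  if (n < 2L * stem) return(FALSE)
  starts <- 1:(n - stem + 1L)
  w <- substring(s, starts, starts + stem - 1L)
  rc <- .revcomp(w)
  for (i in seq_along(w)) {
    js <- which(rc == w[i])
    if (any(abs(starts[js] - starts[i]) >= stem)) return(TRUE)
  }
  FALSE
}

#' Select probes from tiled candidates
#'
#' Candidates failing the GC range, homopolymer, or hairpin-stem screens
#' are removed; survivors are ranked per cluster by closeness of their
#' melting temperature to the cluster's candidate-pool median Tm (ties:
#' smaller start, then shorter length), and the top `per_cluster_limit`
#' are returned. Clusters with no surviving candidate are reported
#' probe-less via the `"probeless"` attribute, not an error.
#'
#' @param candidates Data frame from [tile_candidates()] (one or several
#'   clusters row-bound together).
#' @param constraints [design_constraints()].
#' @return Data frame of selected probes with candidate columns preserved,
#'   ordered by cluster then rank.
#' @export
select_probes <- function(candidates, constraints = design_constraints()) {
  stopifnot(inherits(constraints, "design_constraints"),
            all(c("cluster", "start", "length", "sequence", "gc", "tm")
                %in% names(candidates)))
  probeless <- character(0)
  out <- list()
  for (cl in unique(candidates$cluster)) {
    cc <- candidates[candidates$cluster == cl, , drop = FALSE]
    pool_tm <- stats::median(cc$tm)
    ok <- cc$gc >= constraints$gc_range[1L] &
      cc$gc <= constraints$gc_range[2L] &
      vapply(cc$sequence, .max_homopolymer, numeric(1L)) <=
        constraints$max_homopolymer &
      !vapply(cc$sequence, .has_hairpin, logical(1L),
              stem = constraints$max_hairpin_stem)
    cc <- cc[ok, , drop = FALSE]
    if (nrow(cc) == 0L) {
      probeless <- c(probeless, cl)
      message("cluster ", cl, ": no candidate survived the screens")
      next
    }
    ord <- order(abs(cc$tm - pool_tm), cc$start, cc$length)
    out[[length(out) + 1L]] <-
      utils::head(cc[ord, , drop = FALSE], constraints$per_cluster_limit)
  }
  res <- do.call(rbind, c(list(candidates[0, , drop = FALSE]), out))
  rownames(res) <- NULL
  attr(res, "probeless") <- probeless
  res
}

.TEL_MOTIF <- "TTTAGGG"

#' Is a monomer a telomeric-repeat rotation?
#'
#' TRUE when the monomer is a cyclic rotation of the plant telomeric motif
#' `TTTAGGG` (or a whole-number tandem multiple of it), on either strand.
#'
#' @param monomer A/C/G/T string.
#' @return Logical scalar.
#' @export
is_telomeric <- function(monomer) {
  p <- nchar(monomer)
  if (p %% nchar(.TEL_MOTIF) != 0L) return(FALSE)
  unit <- strrep(.TEL_MOTIF, p %/% nchar(.TEL_MOTIF))
  monomer <- toupper(monomer)
  grepl(monomer, strrep(unit, 2L), fixed = TRUE) ||
    grepl(monomer, strrep(.revcomp(unit), 2L), fixed = TRUE)
}

#' Build a probe id from localization metadata
#'
#' Naming convention: `C{chrom}-{index}` when one chromosome holds at least
#' 30% of the in-silico hits (plurality), `Co-{index}` when hits are
#' dispersed below that cutoff, `Tel-{index}` for telomeric-motif clusters,
#' and `U-{index}` when no localization is available. The chromosome label
#' keeps only its digits (e.g. `chr8` becomes `C8`).
#'
#' @param chrom_hits Named numeric vector of per-chromosome hit counts
#'   (may be empty or NULL for unplaced clusters).
#' @param index Running index within the name prefix.
#' @param monomer Optional consensus monomer, used for the telomeric check.
#' @param dispersal_cutoff Minimum hit share for a chromosome-specific name.
#' @return Probe id string.
#' @export
#' @examples
#' name_probe(c(chr8 = 90, chr1 = 10), 3)        # "C8-3"
#' name_probe(NULL, 1, monomer = "TTTAGGG")      # "Tel-1"
name_probe <- function(chrom_hits, index, monomer = NULL,
                       dispersal_cutoff = 0.30) {
  if (!is.null(monomer) && is_telomeric(monomer))
    return(paste0("Tel-", index))
  if (is.null(chrom_hits) || length(chrom_hits) == 0L ||
      sum(chrom_hits) == 0)
    return(paste0("U-", index))
  share <- chrom_hits / sum(chrom_hits)
  top <- which.max(share)
  if (share[top] >= dispersal_cutoff) {
    num <- gsub("[^0-9]", "", names(chrom_hits)[top])
    if (nchar(num) == 0L) num <- names(chrom_hits)[top]
    paste0("C", num, "-", index)
  } else {
    paste0("Co-", index)
  }
}

#' Assign probe names across clusters
#'
#' Applies [name_probe()] to each cluster in order, maintaining one running
#' index per name prefix so that names are injective within a run.
#'
#' @param hits_by_cluster List (one element per cluster, in order) of named
#'   per-chromosome hit-count vectors; `NULL` elements mean unplaced.
#' @param monomers Optional character vector of consensus monomers, parallel
#'   to `hits_by_cluster`, used for the telomeric check.
#' @return Character vector of probe ids, parallel to the input.
#' @export
assign_probe_names <- function(hits_by_cluster, monomers = NULL) {
  counters <- new.env(parent = emptyenv())
  vapply(seq_along(hits_by_cluster), function(i) {
    mono <- if (is.null(monomers)) NULL else monomers[[i]]
    # find the prefix with a dry run at index 0, then bump its counter
    prefix <- sub("-0$", "", name_probe(hits_by_cluster[[i]], 0, mono))
    idx <- (get0(prefix, envir = counters, ifnotfound = 0L)) + 1L
    assign(prefix, idx, envir = counters)
    paste0(prefix, "-", idx)
  }, character(1L))
}

#' Compose fluorophore cocktails from a channel assignment
#'
#' Builds one probe cocktail (multiplex) per channel, preserving the member
#' order of the assignment. Each probe may appear in exactly one channel.
#' Cocktails are named `Multiplex #1`, `Multiplex #2`, ... in order of first
#' channel appearance.
#'
#' @param probes Data frame with at least a `probe_id` column (the probe
#'   table the assignment refers to).
#' @param assignment Data frame with columns `probe_id` and `channel`.
#' @return Data frame `cocktail, channel, probe_id, position`.
#' @export
compose_cocktails <- function(probes, assignment) {
  stopifnot(is.data.frame(assignment),
            all(c("probe_id", "channel") %in% names(assignment)))
  if (nrow(assignment) == 0L)
    return(data.frame(cocktail = character(), channel = character(),
                      probe_id = character(), position = integer(),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(assignment$probe_id, probes$probe_id)
  if (length(unknown) > 0L)
    stop("unknown probe id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dup <- assignment$probe_id[duplicated(assignment$probe_id)]
  if (length(dup) > 0L)
    stop("probe(s) assigned to more than one channel: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  channels <- unique(assignment$channel)
  out <- lapply(seq_along(channels), function(ci) {
    members <- assignment$probe_id[assignment$channel == channels[ci]]
    data.frame(cocktail = sprintf("Multiplex #%d", ci),
               channel = channels[ci], probe_id = members,
               position = seq_along(members), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
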