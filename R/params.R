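# Parameter constructors with validation. Defaults follow the TRF run and
# filtering rules used to build the probe set: alignment weights 2/7/7,
# minimum score 50, maximum period 2000, array filters period >= 10,
# copies >= 50, percent matches > 70, clustering identity 75%, oligo length
# 40-45 nt, mapping identity > 80% with > 30 matches per bin (oligos) or
# > 1 match/Mb (plasmid-scale probes).

#' Alignment weights for wraparound tandem-repeat scoring
#'
#' Match reward and (positive) mismatch/indel penalties applied negatively,
#' the scoring model under which arrays are detected and re-scored.
#'
#' @param match Match reward (integer score units).
#' @param mismatch Mismatch penalty, stored positive.
#' @param indel Indel penalty, stored positive.
#' @return An object of class `alignment_weights`.
#' @export
#' @examples
#' alignment_weights()           # 2 / 7 / 7
alignment_weights <- function(match = 2, mismatch = 7, indel = 7) {
  stopifnot(length(match) == 1, length(mismatch) == 1, length(indel) == 1,
            match >= 0, mismatch >= 0, indel >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 indel = as.integer(indel)),
            class = "alignment_weights")
}

#' Tandem-repeat detection parameters
#'
#' @param weights [alignment_weights()].
#' @param min_score Minimum reported alignment score (inclusive).
#' @param max_period Maximum monomer period in bp.
#' @param prob_match,prob_indel Percent match/indel probabilities accepted for
#'   parity with TRF's candidate statistics; in this detector they only tune
#'   seed-chain tolerance, `min_score` is the binding filter.
#' @param seed_kmer Exact seed k-mer length (adapted downwards for very short
#'   chromosomes).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(weights = alignment_weights(), min_score = 50,
                             max_period = 2000, prob_match = 80,
                             prob_indel = 10, seed_kmer = 13) {
  stopifnot(inherits(weights, "alignment_weights"),
            min_score > 0, max_period >= 1,
            prob_match > 0, prob_match <= 100,
            prob_indel >= 0, prob_indel < 100,
            seed_kmer >= 3, seed_kmer <= 26)
  structure(list(weights = weights, min_score = as.integer(min_score),
                 max_period = as.integer(max_period),
                 prob_match = prob_match, prob_indel = prob_indel,
                 seed_kmer = as.integer(seed_kmer)),
            class = "detection_params")
}

#' Tandem-repeat array filter parameters
#'
#' Arrays are retained iff `period >= min_period`, `copy_number >=
#' min_copies` and `pct_match > min_pct_match` (strict, as printed).
#'
#' @param min_period Minimum period in bp (inclusive).
#' @param min_copies Minimum copy number (inclusive).
#' @param min_pct_match Percent-match threshold (exclusive).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_period = 10, min_copies = 50,
                          min_pct_match = 70) {
  stopifnot(min_period >= 1, min_copies >= 1,
            min_pct_match >= 0, min_pct_match <= 100)
  structure(list(min_period = min_period, min_copies = min_copies,
                 min_pct_match = min_pct_match),
            class = "filter_params")
}

#' Monomer clustering parameters (greedy incremental, CD-HIT semantics)
#'
#' @param identity_threshold Percent identity for cluster membership
#'   (inclusive).
#' @param consider_reverse_complement Take the better of the two orientations
#'   when computing identity.
#' @param consider_rotations Also maximize identity over cyclic rotations of
#'   the shorter monomer (tandem monomers are rotationally ambiguous; off by
#'   default to match greedy-incremental clustering of linear sequences).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 75,
                           consider_reverse_complement = TRUE,
                           consider_rotations = FALSE) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100)
  structure(list(identity_threshold = identity_threshold,
                 consider_reverse_complement = isTRUE(consider_reverse_complement),
                 consider_rotations = isTRUE(consider_rotations)),
            class = "cluster_params")
}

#' Oligo design constraints
#'
#' @param length_range Allowed probe lengths in nt, `c(min, max)`. Default
#'   40-45; the realized probe set of the source screen spanned 30-50, which
#'   is available by overriding the range.
#' @param gc_range Allowed GC percent range, inclusive.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param max_hairpin_stem Candidates containing a self reverse-complementary
#'   stem of at least this many nt are rejected.
#' @param per_cluster_limit Probes selected per cluster.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(length_range = c(40, 45), gc_range = c(30, 70),
                               max_homopolymer = 6, max_hairpin_stem = 8,
                               per_cluster_limit = 1) {
  stopifnot(length(length_range) == 2, length(gc_range) == 2)
  if (length_range[1] > length_range[2])
    stop("length_range min exceeds max", call. = FALSE)
  stopifnot(length_range[1] >= 1,
            gc_range[1] <= gc_range[2],
            gc_range[1] >= 0, gc_range[2] <= 100,
            max_homopolymer >= 1, max_hairpin_stem >= 1,
            per_cluster_limit >= 1)
  structure(list(length_range = as.integer(length_range),
                 gc_range = gc_range,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_hairpin_stem = as.integer(max_hairpin_stem),
                 per_cluster_limit = as.integer(per_cluster_limit)),
            class = "design_constraints")
}

#' In-silico mapping parameters
#'
#' @param min_identity Percent identity threshold for a window match
#'   (strict: a hit needs identity strictly greater).
#' @param bin_size Locus-calling bin width in bp (fixed bins anchored at 0).
#' @param count_threshold Oligo rule: a bin is called when its hit count is
#'   strictly greater than this.
#' @param density_threshold Plasmid rule: a bin is called when hits per Mb is
#'   strictly greater than this.
#' @param probe_class `"oligo"` or `"plasmid"`.
#' @param plasmid_window,plasmid_step Fragmentation window/step for
#'   plasmid-scale probes.
#' @return An object of class `map_params`.
#' @export
map_params <- function(min_identity = 80, bin_size = 1e6,
                       count_threshold = 30, density_threshold = 1,
                       probe_class = c("oligo", "plasmid"),
                       plasmid_window = 500, plasmid_step = 250) {
  probe_class <- match.arg(probe_class)
  stopifnot(min_identity >= 0, min_identity <= 100, bin_size >= 1,
            count_threshold >= 0, density_threshold >= 0,
            plasmid_window >= 1, plasmid_step >= 1)
  structure(list(min_identity = min_identity, bin_size = as.integer(bin_size),
                 count_threshold = count_threshold,
                 density_threshold = density_threshold,
                 probe_class = probe_class,
                 plasmid_window = as.integer(plasmid_window),
                 plasmid_step = as.integer(plasmid_step)),
            class = "map_params")
}
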