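# Greedy incremental identity clustering of consensus monomers
# (CD-HIT semantics re-implemented at monomer scale, no k-mer pre-filter).

#' Cluster monomers by greedy incremental identity
#'
#' Monomers are sorted by descending length (ties: input order); the first
#' becomes a cluster representative, and each subsequent monomer joins the
#' first existing representative with [global_identity()] at or above the
#' threshold (first-fit, as in greedy-incremental clustering), otherwise it
#' founds a new cluster. Representatives are therefore pairwise below the
#' threshold in founding order, and every representative is the longest
#' member of its cluster.
#'
#' @param monomers Named character vector of monomer sequences (names are
#'   stable ids; unnamed input gets `monomer1..n`).
#' @param params [cluster_params()].
#' @return A data frame with columns `cluster` (integer id in founding
#'   order), `member_id`, `identity` (percent identity to the
#'   representative; 100 for the representative itself) and
#'   `is_representative`.
#' @export
#' @examples
#' greedy_cluster(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTTTTTTTTT"))
greedy_cluster <- function(monomers, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (length(monomers) == 0L) stop("monomers must be non-empty", call. = FALSE)
  monomers <- toupper(monomers)
  if (is.null(names(monomers)))
    names(monomers) <- paste0("monomer", seq_along(monomers))
  for (i in seq_along(monomers)) .check_dna(monomers[[i]], names(monomers)[i])
  ord <- order(-nchar(monomers), seq_along(monomers))
  reps <- integer(0)   # indices (into monomers) of representatives
  rows <- vector("list", length(monomers))
  for (oi in seq_along(ord)) {
    i <- ord[oi]
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      idn <- global_identity(monomers[[i]], monomers[[reps[ci]]], params)
      if (idn >= params$identity_threshold) {
        rows[[i]] <- data.frame(cluster = ci, member_id = names(monomers)[i],
                                identity = idn, is_representative = FALSE,
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rows[[i]] <- data.frame(cluster = length(reps),
                              member_id = names(monomers)[i],
                              identity = 100, is_representative = TRUE,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows[ord])
  res <- res[order(res$cluster, -res$is_representative,
                   match(res$member_id, names(monomers))), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "representatives") <- names(monomers)[reps]
  res
}

#' Representative sequences of a clustering
#'
#' @param clusters Result of [greedy_cluster()].
#' @param monomers The monomer vector the clustering was computed from.
#' @return Named character vector of representative sequences, one per
#'   cluster in founding order.
#' @export
cluster_representatives <- function(clusters, monomers) {
  ids <- clusters$member_id[clusters$is_representative]
  stats::setNames(toupper(monomers)[ids], ids)
}
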