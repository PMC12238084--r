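# Karyotype signal-site tables and cross-accession comparison. A signal
# site is one cataloged probe signal at (chromosome label, arm, region)
# with an intensity class; two karyotypes are diffed by matching reference
# sites against query sites on the (chrom_label, arm, region, probe_id)
# key with intensity compatibility.

SIGNAL_COLUMNS <- c("chrom_label", "arm", "region", "probe_id", "intensity")
.ARMS <- c("short", "long")
.REGIONS <- c("centromere", "terminal", "interstitial")
.INTENSITIES <- c("strong", "weak", "absent")  # absent = absent-on-one-homolog

#' Load a karyotype signal-site table
#'
#' Reads a TSV with header columns `chrom_label, arm, region, probe_id,
#' intensity`. Vocabulary: arm `short|long`; region
#' `centromere|terminal|interstitial`; intensity `strong|weak|absent`
#' (`absent` records a signal missing on one homolog). Unknown values are
#' rejected with the offending line number. Row order is preserved and the
#' table round-trips losslessly through [write_signal_table()].
#'
#' @param path TSV file path (or connection).
#' @return Data frame of signal sites in file order.
#' @export
load_signal_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df), SIGNAL_COLUMNS))
    stop("signal table header must be: ",
         paste(SIGNAL_COLUMNS, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    if (any(is.na(df[i, ]) | df[i, ] == ""))
      stop("line ", line, ": empty field", call. = FALSE)
    if (!df$arm[i] %in% .ARMS)
      stop("line ", line, ": bad arm value \"", df$arm[i], "\"",
           call. = FALSE)
    if (!df$region[i] %in% .REGIONS)
      stop("line ", line, ": bad region value \"", df$region[i], "\"",
           call. = FALSE)
    if (!df$intensity[i] %in% .INTENSITIES)
      stop("line ", line, ": bad intensity value \"", df$intensity[i], "\"",
           call. = FALSE)
  }
  df
}

#' Write a karyotype signal-site table
#'
#' @param sites Signal-site data frame.
#' @param path Output TSV path.
#' @export
write_signal_table <- function(sites, path) {
  stopifnot(identical(names(sites)[seq_along(SIGNAL_COLUMNS)],
                      SIGNAL_COLUMNS))
  utils::write.table(sites[, SIGNAL_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.site_keys <- function(sites, use_region = TRUE) {
  cols <- c("chrom_label", "arm", if (use_region) "region", "probe_id")
  do.call(paste, c(sites[cols], sep = "|"))
}

# strong and weak are mutually compatible intensity classes; a signal
# absent on one homolog only corresponds to the same state
.intensity_compatible <- function(a, b) {
  (a == "absent") == (b == "absent")
}

#' Compare two karyotype signal tables
#'
#' A reference site is matched iff a query site shares its key
#' (`chrom_label, arm, region, probe_id`; drop `region` with
#' `use_region = FALSE` for coarse matching) and has a compatible
#' intensity (`strong`/`weak` are interchangeable; `absent` corresponds
#' only to `absent`). The mismatch percent is rounded half-up to one
#' decimal.
#'
#' @param reference,query Signal-site data frames.
#' @param use_region Include `region` in the matching key.
#' @return A list of class `karyo_comparison`: `total_ref_sites`,
#'   `mismatched`, `mismatch_percent`, `mismatch_list` (keys of unmatched
#'   reference sites).
#' @export
#' @examples
#' ref <- synthetic_signal_catalog(61)
#' qry <- perturb_signal_table(ref, 25, seed = 7)
#' compare_karyotypes(ref, qry)$mismatch_percent   # 41.0
compare_karyotypes <- function(reference, query, use_region = TRUE) {
  rk <- .site_keys(reference, use_region)
  qk <- .site_keys(query, use_region)
  if (anyDuplicated(rk))
    stop("duplicate site key in reference: ", rk[duplicated(rk)][1L],
         call. = FALSE)
  if (anyDuplicated(qk))
    stop("duplicate site key in query: ", qk[duplicated(qk)][1L],
         call. = FALSE)
  idx <- match(rk, qk)
  matched <- !is.na(idx) &
    .intensity_compatible(reference$intensity,
                          ifelse(is.na(idx), "", query$intensity[idx]))
  mismatched <- sum(!matched)
  structure(list(
    total_ref_sites = length(rk),
    mismatched = mismatched,
    mismatch_percent = .round_half_up(100 * mismatched / length(rk), 1L),
    mismatch_list = rk[!matched]),
    class = "karyo_comparison")
}

#' @export
print.karyo_comparison <- function(x, ...) {
  cat(sprintf("karyotype comparison: %d / %d reference sites mismatched (%.1f%%)\n",
              x$mismatched, x$total_ref_sites, x$mismatch_percent))
  invisible(x)
}

#' Count chromosomes bearing a probe's signal
#'
#' Number of distinct chromosome labels carrying at least one signal site
#' of the probe. Homologs count separately only when the table encodes
#' them as separate labels.
#'
#' @param sites Signal-site data frame.
#' @param probe_id Probe name.
#' @return Integer count (0 with a notice for an unknown probe).
#' @export
count_probe_chromosomes <- function(sites, probe_id) {
  sel <- sites$probe_id == probe_id
  if (!any(sel)) {
    message("probe ", probe_id, " has no signal sites")
    return(0L)
  }
  length(unique(sites$chrom_label[sel]))
}

#' Synthetic karyotype signal catalog
#'
#' Builds a deterministic synthetic stand-in for a cataloged karyotype
#' signal table (the published catalog itself is not distributed): sites
#' are laid out over chromosome labels `A01..A10`/`B01..B07` cycling
#' through the 11-oligo probe panel plus `45S`, with unique keys and
#' present (`strong`/`weak`) intensities so perturbations can introduce
#' exact mismatch counts.
#'
#' @param n_sites Number of sites (default 61, the cataloged count).
#' @param seed Seed for the deterministic arm/region/intensity layout.
#' @return Signal-site data frame with `n_sites` rows.
#' @export
synthetic_signal_catalog <- function(n_sites = 61, seed = 1) {
  chroms <- c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:7))
  probes <- c("C8-21", "C4-13", "C10-9", "Co-516", "C10-7", "C5-2", "Tel-1",
              "C1-1", "C1-12", "C10-10", "C5-14", "45S")
  combos <- expand.grid(region = .REGIONS, arm = .ARMS, probe_id = probes,
                        chrom_label = chroms, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  if (n_sites > nrow(combos))
    stop("n_sites exceeds the number of distinct keys", call. = FALSE)
  set.seed(seed)
  pick <- sort(sample.int(nrow(combos), n_sites))
  df <- combos[pick, c("chrom_label", "arm", "region", "probe_id"),
               drop = FALSE]
  df$intensity <- rep_len(c("strong", "weak"), n_sites)
  df <- df[order(df$chrom_label, df$arm, df$region, df$probe_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Perturb a signal table to create a diverged query karyotype
#'
#' Returns a copy of `sites` in which exactly `n_mismatch` sites have had
#' their intensity switched to `absent` (incompatible with a present
#' reference signal), so that [compare_karyotypes()] against the original
#' reports exactly `n_mismatch` mismatches.
#'
#' @param sites Signal-site data frame with present intensities.
#' @param n_mismatch Number of sites to perturb.
#' @param seed Seed selecting which sites are perturbed.
#' @return Perturbed signal-site data frame.
#' @export
perturb_signal_table <- function(sites, n_mismatch, seed = 1) {
  stopifnot(n_mismatch <= nrow(sites))
  present <- which(sites$intensity != "absent")
  if (n_mismatch > length(present))
    stop("not enough present sites to perturb", call. = FALSE)
  set.seed(seed)
  flip <- sample(present, n_mismatch)
  sites$intensity[flip] <- "absent"
  sites
}
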