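# End-to-end orchestration: simulate/load -> detect -> resolve -> filter ->
# cluster -> design -> map -> idiogram, with per-stage item counts in a
# deterministic JSON manifest. Timestamped stage banners go to stderr only,
# so reruns with an identical config are byte-identical.

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_pipeline()]'s
#'   config list.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

.stage_banner <- function(name) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [stage] ", name)
}

.as_params <- function(x, ctor) {
  if (is.null(x)) return(ctor())
  if (inherits(x, class(ctor())[1L])) return(x)
  do.call(ctor, x)
}

#' Run the full probe-design pipeline
#'
#' Executes the stages in published order — tandem-repeat detection,
#' overlap elimination, filtering, consensus clustering, oligo design,
#' probe mapping, idiogram — over a genome FASTA or a simulated genome,
#' writing all intermediate files plus a manifest of stage records
#' (inputs, outputs, parameters, item counts) to the output directory.
#' Probe names are assigned from the in-silico localization
#' ([assign_probe_names()]) during the map stage. Rerunning with an
#' identical config (and seed) reproduces identical outputs byte for byte.
#'
#' Config list entries: `out_dir` (required); one of `genome_fasta` or
#' `simulate` (a list with `chroms` — data frame fields `name`, `length`,
#' `gc` — and optional `plants`, each a list of [plant_spec()] arguments);
#' `seed`; optional `detection`, `filter`, `cluster`, `design`, `map`
#' parameter lists; optional `channels` data frame (`probe_id`, `channel`)
#' for cocktails.
#'
#' @param config Config list (or path to a YAML file).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  det_p <- .as_params(config$detection, detection_params)
  fil_p <- .as_params(config$filter, filter_params)
  clu_p <- .as_params(config$cluster, cluster_params)
  des_p <- .as_params(config$design, design_constraints)
  map_p <- .as_params(config$map, map_params)

  manifest <- list(seed = seed, stages = list())
  record <- function(name, inputs, outputs, parameters, counts) {
    # manifests record file basenames so identical configs give identical
    # manifests regardless of where the output directory lives
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = length(manifest$stages) + 1L, name = name,
           inputs = basename(inputs), outputs = basename(outputs),
           parameters = parameters, counts = counts)
  }
  run_stage <- function(name, fn) {
    .stage_banner(name)
    tryCatch(fn(), error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- input ----------------------------------------------------------------
  genome <- run_stage("input", function() {
    if (!is.null(config$genome_fasta)) {
      g <- read_genome_fasta(config$genome_fasta)
      record("input", config$genome_fasta, character(0), list(),
             list(chromosomes = length(g), bases = sum(nchar(g))))
      g
    } else if (!is.null(config$simulate)) {
      sim <- config$simulate
      plants <- lapply(sim$plants %||% list(), function(pl)
        do.call(plant_spec, pl))
      sg <- generate_genome(as.data.frame(sim$chroms), plants, seed = seed)
      fa <- file.path(out_dir, "genome.fa")
      bed <- file.path(out_dir, "truth.bed")
      write_genome_fasta(sg, fa)
      write_truth_bed(sg$truth, bed)
      record("input", "simulate", c(fa, bed), list(seed = seed),
             list(chromosomes = length(sg$sequences),
                  bases = sum(nchar(sg$sequences)),
                  plants = nrow(sg$truth)))
      sg$sequences
    } else stop("config needs genome_fasta or simulate")
  })
  if (sum(nchar(genome)) == 0L)
    stop("stage scan: genome is empty", call. = FALSE)

  # -- detect / resolve / filter -------------------------------------------
  arrays <- run_stage("detect", function() {
    a <- detect_tandem_repeats(genome, det_p)
    if (nrow(a) == 0L) message("no tandem repeat arrays found")
    f <- file.path(out_dir, "arrays.tsv")
    write_arrays_tsv(a, f)
    record("detect", "genome", f,
           list(min_score = det_p$min_score, max_period = det_p$max_period),
           list(arrays = nrow(a)))
    a
  })
  resolved <- run_stage("resolve", function() {
    r <- resolve_overlaps(arrays)
    f <- file.path(out_dir, "arrays_resolved.tsv")
    write_arrays_tsv(r, f)
    record("resolve", "arrays.tsv", f, list(),
           list(arrays = nrow(r)))
    r
  })
  filtered <- run_stage("filter", function() {
    k <- filter_arrays(resolved, fil_p)
    f <- file.path(out_dir, "arrays_filtered.tsv")
    b <- file.path(out_dir, "arrays_filtered.bed")
    write_arrays_tsv(k, f)
    write_arrays_bed(k, b)
    record("filter", "arrays_resolved.tsv", c(f, b),
           list(min_period = fil_p$min_period, min_copies = fil_p$min_copies,
                min_pct_match = fil_p$min_pct_match),
           list(arrays = nrow(k)))
    k
  })

  # -- cluster --------------------------------------------------------------
  clusters <- run_stage("cluster", function() {
    if (nrow(filtered) == 0L) stop("no arrays left to cluster")
    monomers <- stats::setNames(filtered$consensus,
                                sprintf("TR%04d", seq_len(nrow(filtered))))
    cl <- greedy_cluster(monomers, clu_p)
    reps <- cluster_representatives(cl, monomers)
    f <- file.path(out_dir, "clusters.tsv")
    fa <- file.path(out_dir, "representatives.fa")
    utils::write.table(cl, f, sep = "\t", quote = FALSE, row.names = FALSE)
    write_genome_fasta(reps, fa)
    record("cluster", "arrays_filtered.tsv", c(f, fa),
           list(identity_threshold = clu_p$identity_threshold),
           list(clusters = max(cl$cluster), monomers = nrow(cl)))
    list(table = cl, reps = reps)
  })

  # -- design ---------------------------------------------------------------
  probes <- run_stage("design", function() {
    cands <- do.call(rbind, lapply(seq_along(clusters$reps), function(i)
      tile_candidates(clusters$reps[[i]], des_p,
                      cluster = names(clusters$reps)[i])))
    sel <- select_probes(cands, des_p)
    if (nrow(sel) == 0L) stop("no probe survived the screens")
    f <- file.path(out_dir, "probe_candidates.tsv")
    utils::write.table(sel, f, sep = "\t", quote = FALSE, row.names = FALSE)
    record("design", "representatives.fa", f,
           list(length_range = des_p$length_range,
                gc_range = des_p$gc_range),
           list(candidates = nrow(cands), probes = nrow(sel)))
    sel
  })

  # -- map (scan, name, call) ----------------------------------------------
  mapres <- run_stage("map", function() {
    chrom_lengths <- stats::setNames(nchar(genome), names(genome))
    hits_by_probe <- lapply(seq_len(nrow(probes)), function(i)
      scan_probe(genome, probes$sequence[i],
                 probe_id = probes$cluster[i], params = map_p))
    hit_counts <- lapply(hits_by_probe, function(h)
      if (nrow(h) == 0L) NULL else table(h$chrom))
    ids <- assign_probe_names(
      hit_counts, monomers = clusters$reps[probes$cluster])
    probes$probe_id <- ids
    for (i in seq_along(hits_by_probe))
      if (nrow(hits_by_probe[[i]]) > 0L)
        hits_by_probe[[i]]$probe_id <- ids[i]
    hits <- do.call(rbind, hits_by_probe)
    loci <- bin_and_call(hits, chrom_lengths, map_p)
    fh <- file.path(out_dir, "hits.tsv")
    fl <- file.path(out_dir, "loci.bed")
    fp <- file.path(out_dir, "probes.tsv")
    ff <- file.path(out_dir, "probes.fa")
    utils::write.table(hits, fh, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_loci_bed(loci, fl)
    utils::write.table(probes, fp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_probe_fasta(probes, ff)
    if (!is.null(config$channels)) {
      ck <- compose_cocktails(probes, as.data.frame(config$channels))
      utils::write.table(ck, file.path(out_dir, "cocktails.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    record("map", "probes", c(fh, fl, fp, ff),
           list(min_identity = map_p$min_identity,
                bin_size = map_p$bin_size,
                count_threshold = map_p$count_threshold),
           list(hits = nrow(hits), loci = nrow(loci)))
    list(hits = hits, loci = loci, chrom_lengths = chrom_lengths)
  })

  # -- idiogram -------------------------------------------------------------
  run_stage("idiogram", function() {
    fs <- file.path(out_dir, "idiogram.svg")
    res <- render_idiogram(mapres$loci, mapres$chrom_lengths,
                           svg_path = fs)
    record("idiogram", "loci.bed", c(fs, res$marks_path), list(),
           list(marks = nrow(res$marks)))
    NULL
  })

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
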