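#' Sample records from a simulation
#'
#' Converts a `clip_simulation` into the list-of-samples form consumed by
#' [call_peaks()] and [metagene_pipeline()].
#'
#' @param sim A `clip_simulation`.
#' @return List of sample records (`name`, `role`, `condition`, `reads`,
#'   `library_size`).
#' @export
sim_samples <- function(sim) {
  stopifnot(inherits(sim, "clip_simulation"))
  lapply(seq_len(nrow(sim$config$samples)), function(i) {
    s <- sim$config$samples[i, ]
    list(name = s$name, role = s$role, condition = s$condition,
         reads = sim$reads[[s$name]],
         library_size = sim$config$library_sizes[[s$name]])
  })
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with optional keys `params` (any
#' subset of [clip_params()] fields), `regions` (named list of
#' `[start, end]` pairs), `seed` and `fdr`. Unknown keys and non-positive
#' parameters are rejected with the offending field named. An empty or
#' absent file yields all defaults.
#'
#' @param path Path to a YAML/JSON file, or `NULL` for defaults.
#' @return List of class `run_config` with elements `params`, `regions`,
#'   `seed`, `fdr`.
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path) %||% list()
  }
  allowed <- c("params", "regions", "seed", "fdr")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  overrides <- raw$params %||% list()
  bad <- setdiff(names(overrides), names(formals(clip_params)))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  params <- do.call(clip_params, overrides)
  regions <- if (is.null(raw$regions)) region_annotation() else {
    region_annotation(lapply(raw$regions, as.integer))
  }
  seed <- as.integer(raw$seed %||% 1L)
  fdr <- as.numeric(raw$fdr %||% params$fdr_threshold)
  if (is.na(fdr) || fdr <= 0 || fdr > 1) stop("field 'fdr' must lie in (0, 1]",
                                              call. = FALSE)
  structure(list(params = params, regions = regions, seed = seed, fdr = fdr),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Orchestrates all three analysis stages on a self-generated synthetic
#' experiment: (1) simulate an rRNA experiment with the default
#' expansion-segment footprints and a transcript-locus experiment with one
#' CDS footprint; (2) build per-condition smoothed rRNA enrichment tracks
#' against the truncation control; (3) call knockout-normalized peaks;
#' (4) build knockout-normalized metagene profiles. Every table plus an
#' echo of the effective parameters is written under `out_dir`; a rerun
#' with the same config is byte-identical.
#'
#' @param config A `run_config` (see [load_run_config()]).
#' @param out_dir Output directory.
#' @param n_genes Genes in the transcript-locus simulation.
#' @return Invisibly, a list with `enrichment` (per condition), `peaks`,
#'   `metagene` and the simulation objects.
#' @export
run_clip_pipeline <- function(config = load_run_config(), out_dir,
                              n_genes = 8L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config$params

  message("[simulate] rRNA experiment (seed ", config$seed, ")")
  rsim <- simulate_rrna_experiment(default_rrna_config(seed = config$seed))
  write_simulation(rsim, file.path(out_dir, "sim_rrna"))

  message("[simulate] transcript-locus experiment")
  tlibs <- stats::setNames(rep(1e5, nrow(rsim$config$samples)),
                           rsim$config$samples$name)
  tcfg <- sim_config(rsim$config$samples, tlibs, seed = config$seed + 1L)
  tsim <- simulate_transcriptome_experiment(
    tcfg, n_genes = n_genes,
    footprints = list(transcript_footprint(1, fold = 4, width = 40)))
  write_simulation(tsim, file.path(out_dir, "sim_transcripts"))

  message("[rrna-enrich] truncation-normalized enrichment tracks")
  L <- rsim$config$reference_length
  enr <- list()
  for (cond in unique(rsim$config$samples$condition[rsim$config$samples$role == "ip"])) {
    sm <- rsim$config$samples
    ip_name <- sm$name[sm$role == "ip" & sm$condition == cond][1]
    ct_name <- sm$name[sm$role == "truncation_control" & sm$condition == cond][1]
    if (is.na(ct_name)) stop("[rrna-enrich] no truncation control for condition '",
                             cond, "'", call. = FALSE)
    ip <- coverage_from_reads(rsim$reads[[ip_name]], L,
                              library_size = rsim$config$library_sizes[[ip_name]])
    ct <- coverage_from_reads(rsim$reads[[ct_name]], L,
                              library_size = rsim$config$library_sizes[[ct_name]])
    tr <- rrna_enrichment_pipeline(ip, ct, params, config$regions)
    write_enrichment(tr, file.path(out_dir, paste0("enrichment_", cond, ".tsv")))
    utils::write.table(tr$summary,
                       file.path(out_dir, paste0("enrichment_", cond, "_regions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr[[cond]] <- tr
  }

  message("[callpeaks] knockout-normalized peak calling")
  peaks <- call_peaks(sim_samples(tsim), tsim$annotation, params, config$fdr)
  write_peaks(peaks, file.path(out_dir, "peaks.tsv"),
              bed = file.path(out_dir, "peaks.bed"))

  message("[metagene] knockout-normalized metagene profiles")
  mg <- metagene_pipeline(sim_samples(tsim), tsim$annotation, params)
  utils::write.table(mg, file.path(out_dir, "metagene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(params = unclass(params),
         regions = config$regions, seed = config$seed, fdr = config$fdr,
         n_genes = n_genes),
    file.path(out_dir, "parameters.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")

  invisible(list(enrichment = enr, peaks = peaks, metagene = mg,
                 sim_rrna = rsim, sim_transcripts = tsim))
}
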