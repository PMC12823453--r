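#' Planted footprint
#'
#' A contiguous interval of a reference in which read-start rates of
#' IP-role samples are multiplied by `fold` in the listed conditions.
#' Control-role samples (truncation, knockout) never carry enrichment.
#'
#' @param start,end 1-based inclusive positions.
#' @param fold Multiplicative rate enrichment, >= 0.
#' @param conditions Character vector of simulated conditions carrying the
#'   footprint.
#' @param name Optional label used in error messages and truth records.
#' @return An object of class `footprint`.
#' @examples
#' footprint(1117, 1195, fold = 3)
#' @export
footprint <- function(start, end, fold,
                      conditions = c("untreated", "treated"),
                      name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("footprint must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.numeric(fold) || fold < 0) {
    stop("footprint fold must be >= 0", call. = FALSE)
  }
  structure(list(start = start, end = end, fold = as.numeric(fold),
                 conditions = as.character(conditions),
                 name = name %||% sprintf("fp_%d_%d", start, end)),
            class = "footprint")
}

#' Simulation configuration
#'
#' Describes one synthetic CLIP experiment: a single reference (default the
#' 1869-nt human 18S rRNA length), a flat background read-start rate,
#' planted footprints, per-sample library sizes and roles, a read length
#' and a seed. The same config and seed always reproduce byte-identical
#' output.
#'
#' @param samples Data frame with columns `name`, `role` (one of `ip`,
#'   `truncation_control`, `knockout`) and `condition` (e.g. `untreated`,
#'   `treated`).
#' @param library_sizes Named numeric vector, one total read count per
#'   sample.
#' @param footprints List of [footprint()] objects.
#' @param reference_name,reference_length Reference id and length (nt).
#' @param background_rate Expected read starts per nucleotide per million
#'   library reads; with exact multinomial allocation only its profile
#'   (flat) matters, not its absolute scale.
#' @param read_length Read length in nt: a single value, or `c(min, max)`
#'   for per-read uniform lengths.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(samples, library_sizes, footprints = list(),
                       reference_name = "rna18S", reference_length = 1869L,
                       background_rate = 0.5, read_length = 20L, seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("name", "role", "condition") %in% names(samples)))
  bad <- setdiff(unique(samples$role), c("ip", "truncation_control", "knockout"))
  if (length(bad)) stop("unknown sample role(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!all(samples$name %in% names(library_sizes))) {
    stop("library_sizes must name every sample", call. = FALSE)
  }
  if (any(library_sizes < 0)) stop("library sizes must be >= 0", call. = FALSE)
  reference_length <- as.integer(reference_length)
  if (reference_length < 1L) stop("reference_length must be >= 1", call. = FALSE)
  if (background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  if (!length(read_length) %in% 1:2 || any(read_length < 1)) {
    stop("read_length must be one value or c(min, max), all >= 1", call. = FALSE)
  }
  for (fp in footprints) {
    if (!inherits(fp, "footprint")) stop("footprints must be footprint() objects",
                                         call. = FALSE)
  }
  structure(list(samples = samples,
                 library_sizes = library_sizes[samples$name],
                 footprints = footprints,
                 reference_name = reference_name,
                 reference_length = reference_length,
                 background_rate = background_rate,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default rRNA experiment design
#'
#' The bundled study-like design: one IP sample per condition (untreated,
#' anisomycin-treated), a non-binding truncation control per condition, and
#' one knockout control. Footprints default to the two expansion-segment
#' regions: ES7 (1117-1195, both conditions) and ES6b/c (710-766, treated
#' only), each at threefold enrichment. IP libraries are deep (1e5 reads on
#' the rRNA); control libraries are sparse (800 reads) because a construct
#' that does not bind the ribosome yields little rRNA signal.
#'
#' @param seed Integer RNG seed.
#' @param footprint_fold Enrichment of both default footprints.
#' @param ip_library,control_library Library sizes.
#' @param footprints Override the default footprint list.
#' @return A `sim_config`.
#' @export
default_rrna_config <- function(seed = 1L, footprint_fold = 3,
                                ip_library = 1e5, control_library = 800,
                                footprints = NULL) {
  samples <- data.frame(
    name = c("ip_untreated", "ip_treated", "trunc_untreated", "trunc_treated",
             "ko_untreated"),
    role = c("ip", "ip", "truncation_control", "truncation_control", "knockout"),
    condition = c("untreated", "treated", "untreated", "treated", "untreated"),
    stringsAsFactors = FALSE
  )
  libs <- c(ip_untreated = ip_library, ip_treated = ip_library,
            trunc_untreated = control_library, trunc_treated = control_library,
            ko_untreated = control_library)
  if (is.null(footprints)) {
    footprints <- list(
      footprint(1117, 1195, footprint_fold, c("untreated", "treated"), "ES7"),
      footprint(710, 766, footprint_fold, "treated", "ES6b/c")
    )
  }
  sim_config(samples, libs, footprints, seed = seed)
}

# Per-position expected read-start rates (reads) for one sample.
sample_rates <- function(config, role, condition) {
  rates <- rep(config$background_rate, config$reference_length)
  if (role == "ip") {
    for (fp in config$footprints) {
      if (fp$end > config$reference_length) {
        stop("footprint '", fp$name, "' (", fp$start, "-", fp$end,
             ") lies outside the reference (length ",
             config$reference_length, ")", call. = FALSE)
      }
      if (condition %in% fp$conditions) {
        rates[fp$start:fp$end] <- rates[fp$start:fp$end] * fp$fold
      }
    }
  }
  rates
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

draw_reads <- function(starts1, read_length, reference, reference_length) {
  n <- length(starts1)
  rl <- if (length(read_length) == 2L) {
    sample(seq(read_length[1], read_length[2]), n, replace = TRUE)
  } else rep(read_length, n)
  data.frame(
    reference = rep(reference, n),
    start = starts1 - 1L,
    end = pmin(starts1 - 1L + rl, reference_length),
    name = if (n) sprintf("r%d", seq_len(n)) else character(0),
    score = rep(0L, n),
    strand = rep("+", n),
    stringsAsFactors = FALSE
  )
}

#' Simulate an rRNA CLIP experiment with planted footprints
#'
#' For each sample, the configured library size is allocated exactly over
#' reference positions by a multinomial draw with probabilities
#' proportional to `background_rate` times the footprint fold (IP samples
#' in the footprint's conditions only). Each read then spans `read_length`
#' nucleotides from its start, clipped at the reference end. Reads are
#' single-end on the plus strand of reference coordinates.
#'
#' @param config A [sim_config()].
#' @return An object of class `clip_simulation`: list with `reads` (named
#'   list of read-interval data frames), `truth` (planted footprints,
#'   per-sample expected start rates and echoed generator parameters) and
#'   `config`.
#' @examples
#' sim <- simulate_rrna_experiment(default_rrna_config(seed = 7))
#' names(sim$reads)
#' @export
simulate_rrna_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # validate all footprints up front regardless of sample roles
  for (fp in config$footprints) {
    if (fp$end > config$reference_length) {
      stop("footprint '", fp$name, "' (", fp$start, "-", fp$end,
           ") lies outside the reference (length ",
           config$reference_length, ")", call. = FALSE)
    }
  }
  L <- config$reference_length
  reads <- list()
  expected <- list()
  with_seed(config$seed, {
    for (i in seq_len(nrow(config$samples))) {
      s <- config$samples[i, ]
      lib <- config$library_sizes[[s$name]]
      rates <- sample_rates(config, s$role, s$condition)
      if (sum(rates) <= 0 && lib > 0) {
        stop("all-zero rates for sample '", s$name, "'", call. = FALSE)
      }
      counts <- if (lib > 0) {
        as.vector(stats::rmultinom(1, lib, rates / sum(rates)))
      } else integer(L)
      starts1 <- rep.int(seq_len(L), counts)
      reads[[s$name]] <- draw_reads(starts1, config$read_length,
                                    config$reference_name, L)
      expected[[s$name]] <- rates / sum(rates) * lib
    }
  })
  truth <- list(
    reference_name = config$reference_name,
    reference_length = L,
    read_length = config$read_length,
    background_rate = config$background_rate,
    seed = config$seed,
    samples = config$samples,
    library_sizes = as.list(config$library_sizes),
    footprints = footprints_df(config$footprints),
    expected_start_rates = expected
  )
  structure(list(reads = reads, truth = truth, config = config),
            class = "clip_simulation")
}

footprints_df <- function(footprints) {
  if (!length(footprints)) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), fold = numeric(0),
                      conditions = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    name = vapply(footprints, `[[`, character(1), "name"),
    start = vapply(footprints, `[[`, integer(1), "start"),
    end = vapply(footprints, `[[`, integer(1), "end"),
    fold = vapply(footprints, `[[`, numeric(1), "fold"),
    conditions = vapply(footprints, function(f) paste(f$conditions, collapse = ","),
                        character(1)),
    stringsAsFactors = FALSE
  )
}

#' Footprint on a simulated transcript
#'
#' Places a planted footprint on one gene's canonical transcript, either at
#' explicit transcript coordinates or centered within a region (default
#' the CDS).
#'
#' @param gene Gene index (1-based, in simulation order).
#' @param fold Rate enrichment.
#' @param width Footprint width in nt (used when `start` is NULL).
#' @param start,end Explicit 1-based transcript coordinates (optional).
#' @param region Region to center in when `start` is NULL: `"cds"`,
#'   `"utr5"` or `"utr3"`.
#' @param conditions Conditions carrying the footprint.
#' @return An object of class `transcript_footprint`.
#' @export
transcript_footprint <- function(gene, fold, width = 40L, start = NULL,
                                 end = NULL, region = "cds",
                                 conditions = c("untreated", "treated")) {
  structure(list(gene = as.integer(gene), fold = as.numeric(fold),
                 width = as.integer(width), start = start, end = end,
                 region = match.arg(region, c("cds", "utr5", "utr3")),
                 conditions = as.character(conditions)),
            class = "transcript_footprint")
}

default_length_sampler <- function(n) {
  data.frame(len_5utr = sample(60:180, n, replace = TRUE),
             len_cds = 3L * sample(150:400, n, replace = TRUE),
             len_3utr = sample(100:300, n, replace = TRUE))
}

#' Simulate a transcript-locus CLIP experiment
#'
#' Draws one canonical transcript per gene (plus optional non-canonical
#' decoys), with 5'UTR/CDS/3'UTR lengths from `length_sampler`, and then
#' allocates each sample's library size by one multinomial draw across all
#' transcript positions, exactly as in [simulate_rrna_experiment()].
#' Footprints (see [transcript_footprint()]) enrich IP samples only;
#' knockout and truncation samples are pure background.
#'
#' @param config A [sim_config()]; its reference fields are ignored, its
#'   `footprints` field is not used here (pass `footprints` instead).
#' @param n_genes Number of genes, >= 1.
#' @param length_sampler `function(n)` returning a data.frame with columns
#'   `len_5utr`, `len_cds`, `len_3utr`; the default samples typical human
#'   mRNA region lengths.
#' @param footprints List of [transcript_footprint()] objects.
#' @param decoys_per_gene Non-canonical decoy transcripts per gene; decoys
#'   receive background reads and must be excluded downstream.
#' @return A `clip_simulation` whose `annotation` element is a transcript
#'   table (`gene_id`, `transcript_id`, `canonical`, `strand`, `len_5utr`,
#'   `len_cds`, `len_3utr`) and whose per-sample `reads` use transcript ids
#'   as references.
#' @export
simulate_transcriptome_experiment <- function(config, n_genes,
                                              length_sampler = default_length_sampler,
                                              footprints = list(),
                                              decoys_per_gene = 0L) {
  stopifnot(inherits(config, "sim_config"), n_genes >= 1L)
  for (fp in footprints) {
    if (!inherits(fp, "transcript_footprint")) {
      stop("footprints must be transcript_footprint() objects", call. = FALSE)
    }
    if (fp$gene < 1L || fp$gene > n_genes) {
      stop("footprint gene index ", fp$gene, " outside 1..", n_genes,
           call. = FALSE)
    }
  }
  out <- with_seed(config$seed, {
    lens <- length_sampler(n_genes)
    if (any(lens$len_cds <= 0)) stop("CDS length must be >= 1", call. = FALSE)
    ann <- data.frame(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      transcript_id = sprintf("t%03d", seq_len(n_genes)),
      canonical = 1L,
      strand = "+",
      len_5utr = lens$len_5utr, len_cds = lens$len_cds, len_3utr = lens$len_3utr,
      stringsAsFactors = FALSE
    )
    if (decoys_per_gene > 0L) {
      for (d in seq_len(decoys_per_gene)) {
        dec <- ann[ann$canonical == 1L, ]
        dec$transcript_id <- paste0(dec$transcript_id, ".d", d)
        dec$canonical <- 0L
        ann <- rbind(ann, dec)
      }
    }
    ann$length <- ann$len_5utr + ann$len_cds + ann$len_3utr

    # resolve footprints to absolute transcript coordinates (canonical only)
    truth_fp <- lapply(footprints, function(fp) {
      tr <- ann[ann$canonical == 1L, ][fp$gene, ]
      if (is.null(fp$start)) {
        bounds <- switch(fp$region,
          utr5 = c(1L, tr$len_5utr),
          cds = c(tr$len_5utr + 1L, tr$len_5utr + tr$len_cds),
          utr3 = c(tr$len_5utr + tr$len_cds + 1L, tr$length))
        if (fp$width > bounds[2] - bounds[1] + 1L) {
          stop("footprint width ", fp$width, " exceeds region '", fp$region,
               "' of gene ", fp$gene, call. = FALSE)
        }
        st <- bounds[1] + (bounds[2] - bounds[1] + 1L - fp$width) %/% 2L
        en <- st + fp$width - 1L
      } else {
        st <- as.integer(fp$start); en <- as.integer(fp$end %||% (fp$start + fp$width - 1L))
        if (st < 1L || en > tr$length) {
          stop("footprint ", st, "-", en, " lies outside transcript ",
               tr$transcript_id, " (length ", tr$length, ")", call. = FALSE)
        }
      }
      list(gene = fp$gene, transcript_id = tr$transcript_id, start = st,
           end = en, fold = fp$fold, conditions = fp$conditions)
    })

    offsets <- c(0L, cumsum(ann$length))
    total_len <- offsets[length(offsets)]
    reads <- list()
    expected <- list()
    for (i in seq_len(nrow(config$samples))) {
      s <- config$samples[i, ]
      lib <- config$library_sizes[[s$name]]
      rates <- rep(config$background_rate, total_len)
      if (s$role == "ip") {
        for (fp in truth_fp) {
          if (s$condition %in% fp$conditions) {
            k <- match(fp$transcript_id, ann$transcript_id)
            idx <- (offsets[k] + fp$start):(offsets[k] + fp$end)
            rates[idx] <- rates[idx] * fp$fold
          }
        }
      }
      counts <- if (lib > 0) {
        as.vector(stats::rmultinom(1, lib, rates / sum(rates)))
      } else integer(total_len)
      starts_global <- rep.int(seq_len(total_len), counts)
      tx <- findInterval(starts_global - 1L, offsets[-length(offsets)],
                         rightmost.closed = FALSE)
      starts_local <- starts_global - offsets[tx]
      rl <- config$read_length[1]
      df <- data.frame(
        reference = ann$transcript_id[tx],
        start = starts_local - 1L,
        end = pmin(starts_local - 1L + rl, ann$length[tx]),
        name = if (length(starts_local)) sprintf("r%d", seq_along(starts_local)) else character(0),
        score = 0L, strand = "+", stringsAsFactors = FALSE
      )
      reads[[s$name]] <- df[order(tx, df$start), , drop = FALSE]
      rownames(reads[[s$name]]) <- NULL
      expected[[s$name]] <- rates / sum(rates) * lib
    }
    list(ann = ann, reads = reads, expected = expected, truth_fp = truth_fp)
  })
  fp_df <- if (length(out$truth_fp)) {
    do.call(rbind, lapply(out$truth_fp, function(f) {
      data.frame(gene = f$gene, transcript_id = f$transcript_id,
                 start = f$start, end = f$end, fold = f$fold,
                 conditions = paste(f$conditions, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = integer(0), transcript_id = character(0),
               start = integer(0), end = integer(0), fold = numeric(0),
               conditions = character(0), stringsAsFactors = FALSE)
  }
  truth <- list(
    read_length = config$read_length,
    background_rate = config$background_rate,
    seed = config$seed,
    samples = config$samples,
    library_sizes = as.list(config$library_sizes),
    footprints = fp_df,
    expected_start_rates = out$expected
  )
  structure(list(reads = out$reads, truth = truth, config = config,
                 annotation = out$ann[, c("gene_id", "transcript_id", "canonical",
                                          "strand", "len_5utr", "len_cds",
                                          "len_3utr")]),
            class = "clip_simulation")
}

#' Write a simulation to disk
#'
#' Emits one BED6 file per sample, a `truth.json` record, a sample manifest
#' and, for transcriptome simulations, the annotation table.
#'
#' @param sim A `clip_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "clip_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(sim$reads)) {
    p <- file.path(dir, paste0(nm, ".bed"))
    write_bed(sim$reads[[nm]], p)
    paths[nm] <- p
  }
  manifest <- data.frame(
    sample = sim$config$samples$name,
    role = sim$config$samples$role,
    condition = sim$config$samples$condition,
    path = basename(unname(paths[sim$config$samples$name])),
    library_size = unname(unlist(sim$config$library_sizes[sim$config$samples$name])),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(sim$annotation)) {
    write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  }
  invisible(dir)
}
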