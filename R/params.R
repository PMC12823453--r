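#' Pipeline parameters
#'
#' Bundles every numeric constant of the analysis in one validated record.
#' Defaults reproduce the published analysis settings; any subset can be
#' overridden.
#'
#' @param pseudocount_quantile Quantile of the truncation-control coverage
#'   used as the divide-by-zero pseudocount in the rRNA enrichment ratio
#'   (default 0.001, i.e. the 0.1 percentile).
#' @param low_signal_fraction Positions holding less than this fraction of
#'   cumulative coverage are masked and their fold enrichment set to 1
#'   (default 0.03).
#' @param rrna_smooth_window Rolling-average window for the rRNA enrichment
#'   track, in nucleotides (default 10).
#' @param global_pseudocount Constant added to knockout RPM (and to knockout
#'   read counts in the Poisson expectation) in peak calling (default 5).
#' @param peak_min_fold Peaks require fold enrichment strictly greater than
#'   this (default 2).
#' @param peak_min_run Minimum run length of qualifying positions, in
#'   nucleotides; "more than 20" means runs of at least 21 (default 21).
#' @param peak_min_rpm Peaks require mean per-position IP RPM strictly
#'   greater than this (default 10).
#' @param metagene_bins_per_region Standardized positions per transcript
#'   region (default 100).
#' @param metagene_min_cds Minimum CDS length, in nucleotides, for a
#'   transcript to enter the metagene (default 300).
#' @param metagene_smooth_window Rolling-average window for the metagene
#'   ratio profile (default 5).
#' @param fdr_threshold Benjamini-Hochberg q-value threshold for significant
#'   peaks (default 0.05).
#'
#' @return A named list of class `clip_params`.
#' @examples
#' p <- clip_params()
#' p$peak_min_run
#' clip_params(peak_min_rpm = 20)$peak_min_rpm
#' @export
clip_params <- function(pseudocount_quantile = 0.001,
                        low_signal_fraction = 0.03,
                        rrna_smooth_window = 10,
                        global_pseudocount = 5,
                        peak_min_fold = 2,
                        peak_min_run = 21,
                        peak_min_rpm = 10,
                        metagene_bins_per_region = 100,
                        metagene_min_cds = 300,
                        metagene_smooth_window = 5,
                        fdr_threshold = 0.05) {
  p <- list(
    pseudocount_quantile = pseudocount_quantile,
    low_signal_fraction = low_signal_fraction,
    rrna_smooth_window = rrna_smooth_window,
    global_pseudocount = global_pseudocount,
    peak_min_fold = peak_min_fold,
    peak_min_run = peak_min_run,
    peak_min_rpm = peak_min_rpm,
    metagene_bins_per_region = metagene_bins_per_region,
    metagene_min_cds = metagene_min_cds,
    metagene_smooth_window = metagene_smooth_window,
    fdr_threshold = fdr_threshold
  )
  validate_clip_params(p)
  structure(p, class = "clip_params")
}

validate_clip_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (p$pseudocount_quantile >= 1) {
    stop("parameter 'pseudocount_quantile' must lie in (0, 1)", call. = FALSE)
  }
  if (p$low_signal_fraction >= 1) {
    stop("parameter 'low_signal_fraction' must lie in (0, 1)", call. = FALSE)
  }
  if (p$peak_min_run < 1 || p$peak_min_run != round(p$peak_min_run)) {
    stop("parameter 'peak_min_run' must be a positive integer", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.clip_params <- function(x, ...) {
  cat("CLIP pipeline parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Named regions on the rRNA reference
#'
#' 1-based inclusive intervals used to summarize the enrichment track.
#' Defaults are the two 18S expansion-segment footprint regions: ES7
#' (bases 1117-1195) and ES6b/c (bases 710-766).
#'
#' @param regions Named list; each element `c(start, end)`, 1-based inclusive.
#' @param reference_length Optional length used to validate intervals.
#' @return A data.frame with columns `region`, `start`, `end`.
#' @examples
#' region_annotation()
#' @export
region_annotation <- function(regions = list(ES7 = c(1117L, 1195L),
                                             `ES6b/c` = c(710L, 766L)),
                              reference_length = NULL) {
  stopifnot(is.list(regions), length(regions) >= 1L,
            !is.null(names(regions)), all(nzchar(names(regions))))
  out <- data.frame(
    region = names(regions),
    start = vapply(regions, function(r) as.integer(r[1]), integer(1)),
    end = vapply(regions, function(r) as.integer(r[2]), integer(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (any(out$start < 1L) || any(out$end < out$start)) {
    stop("region intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(reference_length) && any(out$end > reference_length)) {
    bad <- out$region[out$end > reference_length][1]
    stop("region '", bad, "' extends beyond the reference (length ",
         reference_length, ")", call. = FALSE)
  }
  out
}
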