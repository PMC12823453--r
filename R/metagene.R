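#' Filter transcript models for metagene analysis
#'
#' Keeps canonical transcripts with a CDS of at least `min_cds` nucleotides
#' (default 300). Two canonical transcripts for one gene are an error.
#'
#' @param models Transcript table (`gene_id`, `transcript_id`, `canonical`,
#'   `len_5utr`, `len_cds`, `len_3utr`).
#' @param min_cds Minimum CDS length in nt.
#' @return Filtered transcript table.
#' @export
filter_transcripts <- function(models, min_cds = 300) {
  canon <- models[models$canonical == 1L, , drop = FALSE]
  dup <- unique(canon$gene_id[duplicated(canon$gene_id)])
  if (length(dup)) {
    stop("gene(s) with more than one canonical transcript: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- canon[canon$len_cds >= min_cds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linearly rescale a region to a fixed number of bins
#'
#' Samples `nbins` positions evenly spaced over `[0, L - 1]` (endpoints
#' included) with linear interpolation between adjacent original values.
#' `L == nbins` returns the input unchanged; a single-position region
#' broadcasts its value.
#'
#' @param values Per-position signal over the region.
#' @param nbins Number of standardized positions (default 100).
#' @param region Label used in the empty-region message (`L == 0` yields
#'   zeros with a warning for UTRs, an error for the CDS).
#' @return Numeric vector of length `nbins`.
#' @examples
#' scale_region_linear(c(0, 1, 2, 3), 2)  # 0 3
#' @export
scale_region_linear <- function(values, nbins = 100, region = "region") {
  L <- length(values)
  if (L == 0L) {
    if (identical(region, "cds")) {
      stop("cannot scale an empty CDS", call. = FALSE)
    }
    warning("empty ", region, ": filling ", nbins, " bins with 0")
    return(numeric(nbins))
  }
  if (L == nbins) return(as.numeric(values))
  if (L == 1L) return(rep(as.numeric(values), nbins))
  stats::approx(x = seq(0, L - 1), y = as.numeric(values),
                xout = seq(0, L - 1, length.out = nbins))$y
}

#' Standardized 300-bin profile of one transcript
#'
#' Splits a transcript's coverage by its 5'UTR/CDS/3'UTR lengths, rescales
#' each region to 100 positions and concatenates them (bins 0-100 = 5'UTR,
#' 100-200 = CDS, 200-300 = 3'UTR, half-open). Minus-strand transcripts
#' must be reversed upstream so coverage always runs 5' to 3'.
#'
#' @param coverage A `coverage_track` (RPM) or numeric vector covering the
#'   whole transcript.
#' @param model One-row transcript model (`len_5utr`, `len_cds`,
#'   `len_3utr`).
#' @param nbins Bins per region.
#' @return Numeric vector of `3 * nbins` values.
#' @export
transcript_profile <- function(coverage, model, nbins = 100) {
  x <- if (inherits(coverage, "coverage_track")) coverage$counts else as.numeric(coverage)
  lens <- c(model$len_5utr, model$len_cds, model$len_3utr)
  if (length(x) != sum(lens)) {
    stop("coverage length ", length(x), " does not match transcript length ",
         sum(lens), call. = FALSE)
  }
  bounds <- cumsum(lens)
  utr5 <- if (lens[1] > 0) x[seq_len(lens[1])] else numeric(0)
  cds <- x[(bounds[1] + 1):bounds[2]]
  utr3 <- if (lens[3] > 0) x[(bounds[2] + 1):bounds[3]] else numeric(0)
  c(scale_region_linear(utr5, nbins, "5'UTR"),
    scale_region_linear(cds, nbins, "cds"),
    scale_region_linear(utr3, nbins, "3'UTR"))
}

#' Mean metagene profile of one sample
#'
#' Per-bin unweighted mean of [transcript_profile()] over the retained
#' transcripts, from the sample's RPM coverage.
#'
#' @param reads Read-interval data frame (references = transcript ids).
#' @param models Retained transcript table (see [filter_transcripts()]).
#' @param library_size Whole-sample library size for RPM normalization.
#' @param nbins Bins per region.
#' @return List with `bins` (numeric of length `3 * nbins`) and
#'   `n_transcripts`.
#' @export
metagene_profile <- function(reads, models, library_size, nbins = 100) {
  if (nrow(models) == 0L) {
    stop("no transcripts retained for the metagene", call. = FALSE)
  }
  prof <- matrix(0, nrow = nrow(models), ncol = 3 * nbins)
  by_ref <- split(reads, factor(reads$reference, levels = models$transcript_id))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    L <- m$len_5utr + m$len_cds + m$len_3utr
    cov <- rpm_normalize(coverage_from_reads(by_ref[[m$transcript_id]], L,
                                             reference = m$transcript_id,
                                             library_size = library_size))
    prof[i, ] <- transcript_profile(cov, m, nbins)
  }
  list(bins = colMeans(prof), n_transcripts = nrow(models))
}

#' Knockout-normalized, smoothed metagene ratio
#'
#' `ratio[b] = profile[b] / (ko_profile[b] + eps)`, followed by a centered
#' rolling average (window 5 by default). The default `eps` reuses the
#' 0.1-percentile pseudocount rule on the knockout profile.
#'
#' @param profile,ko_profile Equal-length per-bin mean signals (numeric or
#'   the list returned by [metagene_profile()]).
#' @param window Rolling-average window.
#' @param eps Pseudocount; default from
#'   [pseudocount_from_quantile()] on `ko_profile`.
#' @return List with `ratio` and `smoothed` vectors.
#' @export
normalize_and_smooth <- function(profile, ko_profile, window = 5, eps = NULL) {
  a <- if (is.list(profile)) profile$bins else as.numeric(profile)
  b <- if (is.list(ko_profile)) ko_profile$bins else as.numeric(ko_profile)
  stopifnot(length(a) == length(b))
  if (is.null(eps)) eps <- pseudocount_from_quantile(b)
  ratio <- a / (b + eps)
  list(ratio = ratio, smoothed = rolling_average(ratio, window), eps = eps)
}

#' Metagene pipeline (stage 3)
#'
#' Filters transcripts (canonical, CDS >= 300 nt), builds per-condition
#' mean metagene profiles for IP samples, normalizes each to the knockout
#' profile and smooths the ratio.
#'
#' @param samples List of sample records as in [call_peaks()].
#' @param annotation Transcript table.
#' @param params A [clip_params()] record.
#' @return Data frame with `condition`, `bin` (0-299), `region`
#'   (`utr5`/`cds`/`utr3`), `raw_mean`, `ko_mean`, `ko_ratio`, `smoothed`,
#'   plus attribute `n_transcripts`.
#' @export
metagene_pipeline <- function(samples, annotation, params = clip_params()) {
  roles <- vapply(samples, `[[`, character(1), "role")
  if (!any(roles == "knockout")) {
    stop("metagene normalization requires a knockout sample", call. = FALSE)
  }
  nbins <- params$metagene_bins_per_region
  models <- filter_transcripts(annotation, params$metagene_min_cds)
  if (nrow(models) == 0L) stop("no transcripts retained for the metagene",
                               call. = FALSE)
  ko <- samples[roles == "knockout"][[1]]
  ko_prof <- metagene_profile(ko$reads, models, ko$library_size, nbins)
  region <- rep(c("utr5", "cds", "utr3"), each = nbins)
  out <- list()
  for (s in samples[roles == "ip"]) {
    prof <- metagene_profile(s$reads, models, s$library_size, nbins)
    ns <- normalize_and_smooth(prof, ko_prof, params$metagene_smooth_window)
    out[[length(out) + 1L]] <- data.frame(
      condition = s$condition, sample = s$name, bin = seq_len(3 * nbins) - 1L,
      region = region, raw_mean = prof$bins, ko_mean = ko_prof$bins,
      ko_ratio = ns$ratio, smoothed = ns$smoothed, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_transcripts") <- nrow(models)
  res
}
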