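#' Pseudocount from a coverage quantile
#'
#' The divide-by-zero guard for control-normalized ratios: the q-quantile
#' (linear interpolation on sorted values, the common type-7 default) of
#' the control coverage. Sparse controls can make that quantile exactly 0,
#' which would defeat its purpose, so the fallback is the smallest strictly
#' positive value; if the control is all zero, 1.
#'
#' @param control A `coverage_track` or numeric vector.
#' @param q Quantile in (0, 1); default 0.001 (the 0.1 percentile).
#' @return A single positive pseudocount.
#' @examples
#' pseudocount_from_quantile(c(0, 4), 0.001)  # 0.004
#' @export
pseudocount_from_quantile <- function(control, q = 0.001) {
  x <- if (inherits(control, "coverage_track")) control$counts else as.numeric(control)
  if (!length(x)) stop("control track is empty", call. = FALSE)
  stopifnot(q > 0, q < 1)
  v <- stats::quantile(x, q, type = 7, names = FALSE)
  if (v > 0) return(v)
  pos <- x[x > 0]
  if (length(pos)) min(pos) else 1
}

#' Per-position fold enrichment over a control
#'
#' `fold[i] = ip[i] / (control[i] + pc)`.
#'
#' @param ip,control Equal-length `coverage_track`s or numeric vectors (for
#'   the rRNA stage: mean-scaled).
#' @param pc Positive pseudocount added to every control position.
#' @return Numeric vector of fold enrichments.
#' @export
fold_enrichment <- function(ip, control, pc) {
  a <- if (inherits(ip, "coverage_track")) ip$counts else as.numeric(ip)
  b <- if (inherits(control, "coverage_track")) control$counts else as.numeric(control)
  if (length(a) != length(b)) {
    stop("ip and control tracks have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  stopifnot(pc > 0)
  a / (b + pc)
}

#' Low-signal mask
#'
#' Identifies the positions jointly holding less than `fraction` of the
#' cumulative coverage signal: positions are sorted by ascending signal
#' (ties broken by ascending position), and the maximal prefix whose
#' cumulative sum stays strictly below `fraction * total` is masked. Their
#' fold enrichment is later forced to 1.
#'
#' @param signal A `coverage_track` or numeric vector.
#' @param fraction Fraction of cumulative signal to remove, in `[0, 1)`.
#' @return Logical vector, TRUE at masked positions.
#' @examples
#' low_signal_mask(c(1, 2, 3, 94), 0.03)  # only the first position
#' @export
low_signal_mask <- function(signal, fraction = 0.03) {
  x <- if (inherits(signal, "coverage_track")) signal$counts else as.numeric(signal)
  stopifnot(fraction >= 0, fraction < 1)
  mask <- logical(length(x))
  if (fraction == 0 || !length(x)) return(mask)
  ord <- order(x, seq_along(x))
  k <- sum(cumsum(x[ord]) < fraction * sum(x))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Centered rolling average
#'
#' Mean over the window `[i - ceiling(w/2) + 1, i + floor(w/2)]`; even
#' windows therefore extend one position further right than left. At the
#' edges the window shrinks to the available positions.
#'
#' @param values Numeric vector.
#' @param window Window size, >= 1.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' rolling_average(c(0, 0, 10, 0, 0), 5)
#' @export
rolling_average <- function(values, window) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window == 1) return(as.numeric(values))
  zoo::rollapply(as.numeric(values), width = window, FUN = mean,
                 partial = TRUE, align = "center")
}

#' rRNA fold-enrichment pipeline (stage 1)
#'
#' From raw IP and truncation-control coverage to the smoothed
#' control-normalized enrichment track: both tracks are RPM- then
#' mean-scale-normalized; the pseudocount is the 0.1-percentile of the
#' mean-scaled control; the low-signal mask is computed on the IP RPM track
#' and masked positions are set to fold 1 before smoothing with a
#' rolling-average window of 10.
#'
#' @param ip_raw,control_raw Raw `coverage_track`s with library sizes.
#' @param params A [clip_params()] record.
#' @param regions Optional [region_annotation()] for the per-region summary.
#' @return An object of class `enrichment_track`: `reference`, `fold`
#'   (masked positions exactly 1), `mask`, `smoothed`, `pseudocount`, and
#'   a `summary` data.frame (max and mean of both raw and smoothed fold per
#'   region) when `regions` is supplied.
#' @examples
#' sim <- simulate_rrna_experiment(default_rrna_config(seed = 1))
#' ip <- coverage_from_reads(sim$reads$ip_untreated, 1869)
#' ct <- coverage_from_reads(sim$reads$trunc_untreated, 1869)
#' enr <- rrna_enrichment_pipeline(ip, ct)
#' enr$summary
#' @export
rrna_enrichment_pipeline <- function(ip_raw, control_raw,
                                     params = clip_params(),
                                     regions = region_annotation()) {
  stopifnot(inherits(ip_raw, "coverage_track"),
            inherits(control_raw, "coverage_track"))
  ip_rpm <- rpm_normalize(ip_raw)
  ctl_rpm <- rpm_normalize(control_raw)
  ip_ms <- mean_scale(ip_rpm)
  ctl_ms <- mean_scale(ctl_rpm)
  pc <- pseudocount_from_quantile(ctl_ms, params$pseudocount_quantile)
  fold <- fold_enrichment(ip_ms, ctl_ms, pc)
  mask <- low_signal_mask(ip_rpm, params$low_signal_fraction)
  fold[mask] <- 1
  smoothed <- rolling_average(fold, params$rrna_smooth_window)
  out <- structure(list(reference = ip_raw$reference, fold = fold,
                        mask = mask, smoothed = smoothed, pseudocount = pc),
                   class = "enrichment_track")
  if (!is.null(regions)) {
    regions <- region_annotation(
      stats::setNames(lapply(seq_len(nrow(regions)),
                             function(i) c(regions$start[i], regions$end[i])),
                      regions$region),
      reference_length = length(fold))
    out$summary <- region_summary(out, regions)
  }
  out
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf("<enrichment_track> %s: %d nt, %d masked, max smoothed fold %.3g\n",
              x$reference, length(x$fold), sum(x$mask), max(x$smoothed)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Summarize an enrichment track over named regions
#'
#' @param track An `enrichment_track`.
#' @param regions A [region_annotation()] data.frame.
#' @return Data frame with per-region max/mean of the raw and smoothed fold.
#' @export
region_summary <- function(track, regions = region_annotation()) {
  stopifnot(inherits(track, "enrichment_track"))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    idx <- regions$start[i]:regions$end[i]
    data.frame(region = regions$region[i], start = regions$start[i],
               end = regions$end[i],
               max_fold = max(track$fold[idx]),
               mean_fold = mean(track$fold[idx]),
               max_smoothed = max(track$smoothed[idx]),
               mean_smoothed = mean(track$smoothed[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average enrichment tracks across replicates
#'
#' Fold is computed per replicate, then averaged position-wise (raw and
#' smoothed components alike); a position is masked in the average only if
#' masked in every replicate.
#'
#' @param tracks List of `enrichment_track`s on the same reference.
#' @return An `enrichment_track`.
#' @export
average_enrichment <- function(tracks) {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "enrichment_track")))
  lens <- vapply(tracks, function(t) length(t$fold), integer(1))
  if (length(unique(lens)) != 1L) stop("tracks have different lengths", call. = FALSE)
  structure(list(
    reference = tracks[[1]]$reference,
    fold = rowMeans(sapply(tracks, `[[`, "fold")),
    mask = Reduce(`&`, lapply(tracks, `[[`, "mask")),
    smoothed = rowMeans(sapply(tracks, `[[`, "smoothed")),
    pseudocount = mean(vapply(tracks, `[[`, numeric(1), "pseudocount"))
  ), class = "enrichment_track")
}

#' Write an enrichment track as TSV (and optionally bedGraph)
#'
#' @param track An `enrichment_track`.
#' @param path Output TSV path (columns `pos_1based`, `fold`, `masked`,
#'   `smoothed`).
#' @param bedgraph Optional path for the smoothed track in bedGraph format.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(track, path, bedgraph = NULL) {
  df <- data.frame(pos_1based = seq_along(track$fold),
                   fold = track$fold,
                   masked = as.integer(track$mask),
                   smoothed = track$smoothed)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedgraph)) {
    write_bedgraph(coverage_track(track$smoothed, track$reference, 0), bedgraph)
  }
  invisible(path)
}
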