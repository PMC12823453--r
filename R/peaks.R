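#' Knockout-normalized fold track for peak calling
#'
#' For transcript loci no mean-scaling is applied: the fold is IP RPM over
#' knockout RPM with a global pseudocount, `ip[i] / (ko[i] + global_pc)`.
#' Positions failing the per-locus low-signal filter (less than 3% of the
#' cumulative IP coverage) are forced to fold 1.
#'
#' @param ip_rpm,ko_rpm Equal-length RPM `coverage_track`s (or numeric
#'   vectors) for one locus.
#' @param params A [clip_params()] record (`global_pseudocount`,
#'   `low_signal_fraction`).
#' @return Numeric fold vector.
#' @export
ko_fold_track <- function(ip_rpm, ko_rpm, params = clip_params()) {
  a <- if (inherits(ip_rpm, "coverage_track")) ip_rpm$counts else as.numeric(ip_rpm)
  b <- if (inherits(ko_rpm, "coverage_track")) ko_rpm$counts else as.numeric(ko_rpm)
  if (length(a) != length(b)) {
    stop("ip and knockout tracks have different lengths (", length(a),
         " vs ", length(b), ")", call. = FALSE)
  }
  fold <- a / (b + params$global_pseudocount)
  fold[low_signal_mask(a, params$low_signal_fraction)] <- 1
  fold
}

#' Candidate peak runs
#'
#' Maximal runs of consecutive positions with fold enrichment strictly
#' greater than `peak_min_fold`, kept when longer than 20 nt (length >=
#' `peak_min_run`) and when the mean per-position IP RPM over the run
#' strictly exceeds `peak_min_rpm`. Both thresholds are strict: a run of
#' exactly 20 positions, or fold exactly at the threshold, never qualifies.
#'
#' @param fold Fold-enrichment vector.
#' @param ip_rpm Equal-length IP RPM vector.
#' @param params A [clip_params()] record.
#' @return Data frame with 1-based inclusive `start`, `end`, `length`,
#'   `mean_fold`, `mean_rpm`.
#' @export
candidate_runs <- function(fold, ip_rpm, params = clip_params()) {
  ip_rpm <- if (inherits(ip_rpm, "coverage_track")) ip_rpm$counts else as.numeric(ip_rpm)
  stopifnot(length(fold) == length(ip_rpm))
  r <- rle(fold > params$peak_min_fold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$peak_min_run
  out <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(out)) {
    out$length <- out$end - out$start + 1L
    out$mean_fold <- mapply(function(s, e) mean(fold[s:e]), out$start, out$end)
    out$mean_rpm <- mapply(function(s, e) mean(ip_rpm[s:e]), out$start, out$end)
    out <- out[out$mean_rpm > params$peak_min_rpm, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$length <- integer(0); out$mean_fold <- numeric(0); out$mean_rpm <- numeric(0)
  }
  out
}

#' One-sided (upper-tail) Poisson p-value
#'
#' `P(X >= observed)` for `X ~ Poisson(lambda)`; 1 when `observed == 0`.
#'
#' @param observed Non-negative integer count (vectorized).
#' @param lambda Expected count, > 0 (vectorized).
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' poisson_upper_p(5, 1)   # 0.003660
#' poisson_upper_p(2, 2)   # 0.593994
#' @export
poisson_upper_p <- function(observed, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed must be a non-negative integer", call. = FALSE)
  }
  stats::ppois(observed - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Observed and expected read counts for a candidate run
#'
#' The Poisson test statistic: `observed` is the number of IP reads
#' overlapping the run; the expectation is the knockout read count over the
#' run plus the global pseudocount, scaled by the library-size ratio:
#' `lambda = (ko_count + global_pc) * ip_lib / ko_lib`. A coverage-sum mode
#' (summing raw per-position coverage instead of counting reads) is
#' available for comparison but over-disperses the Poisson by roughly the
#' read length.
#'
#' @param run One-row data.frame (or list) with 1-based inclusive `start`,
#'   `end`.
#' @param ip_reads,ko_reads Read-interval data frames for the locus
#'   (0-based half-open).
#' @param ip_lib,ko_lib Library sizes (whole sample), both > 0.
#' @param params A [clip_params()] record.
#' @param count_mode `"reads"` (default) or `"coverage"`.
#' @param reference_length Needed for `count_mode = "coverage"`.
#' @return List with `observed` and `lambda`.
#' @export
peak_statistics <- function(run, ip_reads, ko_reads, ip_lib, ko_lib,
                            params = clip_params(),
                            count_mode = c("reads", "coverage"),
                            reference_length = NULL) {
  count_mode <- match.arg(count_mode)
  if (ko_lib <= 0) stop("knockout library size must be > 0", call. = FALSE)
  if (ip_lib <= 0) stop("ip library size must be > 0", call. = FALSE)
  s0 <- run$start - 1L  # 0-based
  e0 <- run$end         # half-open
  if (count_mode == "reads") {
    observed <- sum(ip_reads$start < e0 & ip_reads$end > s0)
    ko_n <- sum(ko_reads$start < e0 & ko_reads$end > s0)
  } else {
    stopifnot(!is.null(reference_length))
    idx <- run$start:run$end
    observed <- sum(coverage_from_reads(ip_reads, reference_length)$counts[idx])
    ko_n <- sum(coverage_from_reads(ko_reads, reference_length)$counts[idx])
  }
  list(observed = as.integer(round(observed)),
       lambda = (ko_n + params$global_pseudocount) * ip_lib / ko_lib)
}

#' Call CLIP peaks against the knockout control
#'
#' For each canonical transcript and each condition with an IP sample:
#' build IP and knockout RPM coverage, form the knockout-normalized fold
#' track, extract candidate runs, compute the one-sided Poisson test on
#' overlapping read counts, and adjust across all candidate peaks of the
#' condition with Benjamini-Hochberg. Output is deterministic and sorted by
#' q-value, then locus, then position.
#'
#' @param samples List of sample records, each a list with `name`, `role`
#'   (`ip` / `knockout` / `truncation_control`), `condition`, `reads`
#'   (read-interval data.frame whose `reference` column holds transcript
#'   ids) and `library_size`. One knockout is required; if no knockout
#'   matches a condition, the first knockout sample is used for all
#'   conditions.
#' @param annotation Transcript table (`gene_id`, `transcript_id`,
#'   `canonical`, `len_5utr`, `len_cds`, `len_3utr`); only canonical
#'   transcripts are used.
#' @param params A [clip_params()] record.
#' @param fdr Reporting threshold on the q-value; `NULL` returns all
#'   candidate peaks.
#' @param count_mode Passed to [peak_statistics()].
#' @return Data frame of peaks: `condition`, `sample`, `locus`,
#'   `start`, `end` (1-based inclusive), `length`, `mean_fold`, `mean_rpm`,
#'   `observed`, `lambda`, `pvalue`, `qvalue`.
#' @export
call_peaks <- function(samples, annotation, params = clip_params(),
                       fdr = params$fdr_threshold,
                       count_mode = c("reads", "coverage")) {
  count_mode <- match.arg(count_mode)
  roles <- vapply(samples, `[[`, character(1), "role")
  if (!any(roles == "knockout")) {
    stop("peak calling requires a knockout sample", call. = FALSE)
  }
  ko_all <- samples[roles == "knockout"]
  ann <- annotation[annotation$canonical == 1L, , drop = FALSE]
  ann$length <- ann$len_5utr + ann$len_cds + ann$len_3utr

  empty <- data.frame(condition = character(0), sample = character(0),
                      locus = character(0), start = integer(0), end = integer(0),
                      length = integer(0), mean_fold = numeric(0),
                      mean_rpm = numeric(0), observed = integer(0),
                      lambda = numeric(0), pvalue = numeric(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE)
  rows <- list()
  for (s in samples[roles == "ip"]) {
    ko_match <- Filter(function(k) k$condition == s$condition, ko_all)
    ko <- if (length(ko_match)) ko_match[[1]] else ko_all[[1]]
    by_ref_ip <- split(s$reads, factor(s$reads$reference, levels = ann$transcript_id))
    by_ref_ko <- split(ko$reads, factor(ko$reads$reference, levels = ann$transcript_id))
    for (i in seq_len(nrow(ann))) {
      tid <- ann$transcript_id[i]
      L <- ann$length[i]
      ipr <- by_ref_ip[[tid]]
      kor <- by_ref_ko[[tid]]
      ip_rpm <- rpm_normalize(coverage_from_reads(ipr, L, reference = tid,
                                                  library_size = s$library_size))
      ko_rpm <- rpm_normalize(coverage_from_reads(kor, L, reference = tid,
                                                  library_size = ko$library_size))
      fold <- ko_fold_track(ip_rpm, ko_rpm, params)
      runs <- candidate_runs(fold, ip_rpm, params)
      if (!nrow(runs)) next
      for (j in seq_len(nrow(runs))) {
        st <- peak_statistics(runs[j, ], ipr, kor, s$library_size,
                              ko$library_size, params, count_mode, L)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = s$condition, sample = s$name, locus = tid,
          start = runs$start[j], end = runs$end[j], length = runs$length[j],
          mean_fold = runs$mean_fold[j], mean_rpm = runs$mean_rpm[j],
          observed = st$observed, lambda = st$lambda,
          pvalue = poisson_upper_p(st$observed, st$lambda),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  peaks <- do.call(rbind, rows)
  peaks$qvalue <- stats::ave(peaks$pvalue, peaks$condition, FUN = bh_adjust)
  if (!is.null(fdr)) peaks <- peaks[peaks$qvalue < fdr, , drop = FALSE]
  peaks <- peaks[order(peaks$qvalue, peaks$locus, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Write peaks as TSV and significant peaks as BED6
#'
#' @param peaks Peak table from [call_peaks()].
#' @param path TSV output path.
#' @param bed Optional BED6 path (0-based half-open, score = -log10 q).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, bed = NULL) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed) && nrow(peaks)) {
    write_bed(data.frame(reference = peaks$locus,
                         start = peaks$start - 1L,
                         end = peaks$end,
                         name = sprintf("peak%d", seq_len(nrow(peaks))),
                         score = round(-log10(pmax(peaks$qvalue, 1e-300)), 3),
                         strand = "+"),
              bed)
  }
  invisible(path)
}
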