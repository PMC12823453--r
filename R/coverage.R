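#' Per-position coverage track
#'
#' A coverage track holds raw or normalized read depth over a single
#' reference sequence, together with the library size (total deduplicated
#' reads of the sample) that RPM normalization divides by. The `units` tag
#' tracks the normalization state and may only move forward:
#' `raw` -> `rpm` -> `mean_scaled`.
#'
#' @param counts Numeric vector of per-position values (length = reference
#'   length), all non-negative.
#' @param reference Reference sequence name.
#' @param library_size Total deduplicated reads in the sample (a count; may
#'   exceed the reads on this reference).
#' @param units One of `"raw"`, `"rpm"`, `"mean_scaled"`.
#' @return An object of class `coverage_track`.
#' @examples
#' coverage_track(c(0, 2, 3), "chrR", library_size = 5)
#' @export
coverage_track <- function(counts, reference, library_size,
                           units = c("raw", "rpm", "mean_scaled")) {
  units <- match.arg(units)
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("coverage track must have length >= 1", call. = FALSE)
  if (anyNA(counts) || any(counts < 0)) {
    stop("coverage counts must be non-negative and finite", call. = FALSE)
  }
  if (!is.numeric(library_size) || length(library_size) != 1L || library_size < 0) {
    stop("library_size must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(reference = as.character(reference), counts = counts,
         library_size = as.numeric(library_size), units = units),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d nt, units=%s, library_size=%g, mean=%.4g\n",
              x$reference, length(x$counts), x$units, x$library_size,
              mean(x$counts)))
  invisible(x)
}

#' @export
length.coverage_track <- function(x) length(x$counts)

#' Build a raw coverage track from read intervals
#'
#' Every position a read spans contributes one unit of depth (full-span
#' coverage, not 5' end counting). Reads are 0-based half-open intervals on
#' a single reference.
#'
#' @param reads Data frame of read intervals with columns `start` (0-based)
#'   and `end` (half-open); a `reference` column, if present, must be
#'   constant.
#' @param reference_length Length of the reference in nucleotides.
#' @param reference Reference name; defaults to the reads' reference.
#' @param library_size Library size recorded on the track; defaults to
#'   `nrow(reads)` (appropriate when the sample's reads all map to this
#'   reference).
#' @return A `coverage_track` with `units = "raw"`.
#' @examples
#' reads <- data.frame(start = c(0, 5), end = c(10, 15))
#' coverage_from_reads(reads, 20)
#' @export
coverage_from_reads <- function(reads, reference_length, reference = NULL,
                                library_size = NULL) {
  reference_length <- as.integer(reference_length)
  stopifnot(reference_length >= 1L)
  if (!is.null(reads$reference)) {
    refs <- unique(reads$reference)
    if (length(refs) > 1L) {
      stop("reads span multiple references: ", paste(refs, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(reference) && length(refs) == 1L) reference <- refs
  }
  if (is.null(reference)) reference <- "ref"
  if (nrow(reads) == 0L) {
    return(coverage_track(numeric(reference_length), reference,
                          library_size %||% 0))
  }
  s <- as.integer(reads$start)
  e <- as.integer(reads$end)
  if (any(s < 0L) || any(e <= s) || any(e > reference_length)) {
    stop("read intervals must satisfy 0 <= start < end <= reference length",
         call. = FALSE)
  }
  # difference-array accumulation: +1 at start, -1 one past the end
  add <- tabulate(s + 1L, nbins = reference_length)
  sub <- tabulate(e + 1L, nbins = reference_length + 1L)
  counts <- cumsum(add - sub[seq_len(reference_length)])
  coverage_track(counts, reference, library_size %||% nrow(reads))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reads-per-million normalization
#'
#' Scales raw coverage by `1e6 / library_size`.
#'
#' @param track A raw `coverage_track` with `library_size > 0`.
#' @return The track with `units = "rpm"`.
#' @examples
#' t <- coverage_track(c(4, 0), "chrR", library_size = 2e6)
#' rpm_normalize(t)$counts  # 2, 0
#' @export
rpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "raw") {
    stop("rpm_normalize expects units 'raw', got '", track$units, "'",
         call. = FALSE)
  }
  if (track$library_size <= 0) stop("empty library", call. = FALSE)
  track$counts <- track$counts / track$library_size * 1e6
  track$units <- "rpm"
  track
}

#' Mean-scale normalization
#'
#' Divides an RPM track by its mean so the regional mean becomes exactly 1.
#'
#' @param track An RPM `coverage_track` with positive mean.
#' @return The track with `units = "mean_scaled"`.
#' @examples
#' t <- rpm_normalize(coverage_track(c(2, 4, 6), "chrR", 1e6))
#' mean_scale(t)$counts  # 0.5, 1.0, 1.5
#' @export
mean_scale <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "rpm") {
    stop("mean_scale expects units 'rpm', got '", track$units, "'",
         call. = FALSE)
  }
  m <- mean(track$counts)
  if (m <= 0) stop("cannot mean-scale an all-zero track", call. = FALSE)
  track$counts <- track$counts / m
  track$units <- "mean_scaled"
  track
}
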