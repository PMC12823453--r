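#' Read aligned intervals or coverage from standard formats
#'
#' BED6 files (0-based, half-open) yield a read-interval data frame;
#' bedGraph files yield a dense raw `coverage_track`. Parsing goes through
#' rtracklayer after a light line-level check so malformed input is reported
#' with its line number.
#'
#' @param path File path.
#' @param format `"BED"` or `"bedGraph"`.
#' @param reference_length Declared reference length; intervals beyond it
#'   are an error. Required for bedGraph (sets the track length).
#' @param library_size Library size attached to a bedGraph track (the
#'   sample manifest supplies it; reads-per-million needs the whole-sample
#'   read count, not the on-reference count).
#' @return For BED, a data.frame with columns `reference`, `start` (0-based),
#'   `end` (half-open), `name`, `score`, `strand`; for bedGraph, a
#'   `coverage_track`.
#' @export
read_intervals <- function(path, format = c("BED", "bedGraph"),
                           reference_length = NULL, library_size = NA) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_interval_lines(path, min_fields = if (format == "BED") 3L else 4L)
  if (format == "BED") {
    gr <- rtracklayer::import(path, format = "BED")
    n <- length(gr)
    reads <- data.frame(
      reference = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, n),
      score = if (!is.null(gr$score)) as.numeric(gr$score) else rep(0, n),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    if (!is.null(reference_length) && nrow(reads) > 0L &&
        any(reads$end > reference_length)) {
      stop("interval beyond declared reference length ", reference_length,
           call. = FALSE)
    }
    reads
  } else {
    if (is.null(reference_length)) {
      stop("reference_length is required for bedGraph input", call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "bedGraph")
    counts <- numeric(reference_length)
    if (length(gr) > 0L) {
      if (any(GenomicRanges::end(gr) > reference_length)) {
        stop("interval beyond declared reference length ", reference_length,
             call. = FALSE)
      }
      for (i in seq_along(gr)) {
        counts[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- gr$score[i]
      }
    }
    ref <- if (length(gr) > 0L) {
      as.character(GenomicRanges::seqnames(gr))[1]
    } else "ref"
    coverage_track(counts, ref, library_size = if (is.na(library_size)) 0 else library_size)
  }
}

# Field-count / numeric sanity check that reports the offending line number.
check_interval_lines <- function(path, min_fields) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "track") || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < min_fields ||
        anyNA(suppressWarnings(as.numeric(fields[2:3])))) {
      stop("malformed line ", i, " in ", basename(path), ": '", ln, "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write read intervals as BED6
#'
#' @param reads Read-interval data frame (`reference`, `start` 0-based,
#'   `end` half-open; optional `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  n <- nrow(reads)
  name <- reads$name %||% sprintf("r%d", seq_len(n))
  if (n > 0L && anyNA(name)) name <- sprintf("r%d", seq_len(n))
  score <- reads$score %||% rep(0L, n)
  strand <- reads$strand %||% rep("+", n)
  lines <- if (n == 0L) character(0) else {
    paste(reads$reference, format(reads$start, scientific = FALSE, trim = TRUE),
          format(reads$end, scientific = FALSE, trim = TRUE),
          name, score, strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed to one line (dense dialect: every
#' position of the reference is covered by some line, including zeros).
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  lines <- paste(track$reference,
                 format(starts, scientific = FALSE, trim = TRUE),
                 format(ends, scientific = FALSE, trim = TRUE),
                 format(r$values, scientific = FALSE, trim = TRUE, digits = 15),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a transcript annotation table
#'
#' Tab-separated with columns `gene_id`, `transcript_id`, `canonical`
#' (0/1), `strand`, `len_5utr`, `len_cds`, `len_3utr`.
#'
#' @param path File path.
#' @return A data.frame of transcript models.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "transcript_id", "canonical", "strand",
              "len_5utr", "len_cds", "len_3utr")
  missing <- setdiff(needed, names(ann))
  if (length(missing)) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' @rdname read_annotation
#' @param annotation Transcript-model data.frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with columns `sample`, `role` (one of `ip`,
#' `truncation_control`, `knockout`), `condition`, `path`, `library_size`.
#'
#' @param path File path.
#' @return A data.frame, validated.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample", "role", "condition", "path", "library_size")
  missing <- setdiff(needed, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(m$role), c("ip", "truncation_control", "knockout"))
  if (length(bad)) stop("unknown sample role(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  m
}
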