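# Independent oracles and small fixture builders used across the suite.

# Upper-tail Poisson probability by direct pmf summation in log space,
# from `observed` out to observed + 20 standard deviations.
brute_poisson_upper <- function(observed, lambda) {
  if (observed == 0) return(1)
  kmax <- max(observed, ceiling(lambda + 20 * sqrt(lambda))) + 25L
  k <- observed:kmax
  sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# Benjamini-Hochberg step-up by hand: sort ascending, q_(i) is the
# running minimum over j >= i of min(1, p_(j) * n / j), mapped back.
hand_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  raw <- pmin(1, (n / seq_len(n)) * ps)
  q <- rev(cummin(rev(raw)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Exact expected full-span coverage given per-position expected read-start
# counts: position i is covered by reads starting in (i - rl, i].
expected_coverage_from_starts <- function(start_rates, read_length) {
  L <- length(start_rates)
  cs <- c(0, cumsum(start_rates))
  vapply(seq_len(L), function(i) {
    cs[i + 1] - cs[max(0L, i - read_length) + 1]
  }, numeric(1))
}

# Two-sample design (one IP per condition + knockout) for locus simulations.
two_cond_samples <- function() {
  data.frame(name = c("ip_u", "ip_t", "ko"),
             role = c("ip", "ip", "knockout"),
             condition = c("untreated", "treated", "untreated"),
             stringsAsFactors = FALSE)
}

ip_ko_samples <- function() {
  data.frame(name = c("ip", "ko"), role = c("ip", "knockout"),
             condition = c("untreated", "untreated"), stringsAsFactors = FALSE)
}

# Manual read-interval data frame on one reference.
make_reads <- function(starts, read_length, reference = "tx", L = NULL) {
  end <- starts + read_length
  if (!is.null(L)) end <- pmin(end, L)
  n <- length(starts)
  data.frame(reference = rep(reference, n), start = as.integer(starts),
             end = as.integer(end), name = sprintf("r%d", seq_len(n)),
             score = rep(0L, n), strand = rep("+", n),
             stringsAsFactors = FALSE)
}

# One-gene annotation table.
one_tx_annotation <- function(len_5utr, len_cds, len_3utr,
                              transcript_id = "tx", canonical = 1L) {
  data.frame(gene_id = "g1", transcript_id = transcript_id,
             canonical = canonical, strand = "+",
             len_5utr = len_5utr, len_cds = len_cds, len_3utr = len_3utr,
             stringsAsFactors = FALSE)
}

# Jaccard index of two 1-based inclusive intervals.
interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0L, min(a_end, b_end) - max(a_start, b_start) + 1L)
  union <- (a_end - a_start + 1L) + (b_end - b_start + 1L) - inter
  inter / union
}
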