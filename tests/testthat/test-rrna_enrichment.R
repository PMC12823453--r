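rpm_track <- function(x, lib = 1e6) {
  rpm_normalize(coverage_track(x, "chrR", library_size = lib))
}

test_that("mean scaling divides by the regional mean", {
  t <- mean_scale(rpm_track(c(2, 4, 6)))
  expect_equal(t$counts, c(0.5, 1.0, 1.5))
  expect_equal(t$units, "mean_scaled")

  expect_equal(mean_scale(rpm_track(rep(7, 10)))$counts, rep(1, 10))

  set.seed(31)
  for (i in 1:10) {
    expect_equal(mean(mean_scale(rpm_track(runif(50, 0, 10) + 0.1))$counts), 1)
  }
  expect_error(mean_scale(rpm_track(rep(0, 5))), "all-zero")
  expect_error(mean_scale(coverage_track(1:3, "chrR", 10)), "units 'rpm'")
})

test_that("quantile pseudocount follows type-7 interpolation with fallbacks", {
  expect_equal(pseudocount_from_quantile(c(0, 4), 0.001), 0.004)
  expect_equal(pseudocount_from_quantile(rep(2.5, 100), 0.001), 2.5)
  expect_equal(pseudocount_from_quantile(rep(0, 50), 0.001), 1)
  # sparse control: quantile 0 falls back to the smallest positive value
  expect_equal(pseudocount_from_quantile(c(0, 0, 0, 0, 7, 5), 0.001), 5)
})

test_that("fold enrichment is ip over pseudocounted control", {
  expect_equal(fold_enrichment(rep(1, 5), rep(1, 5), pc = 1), rep(0.5, 5))
  expect_equal(fold_enrichment(rep(0, 4), runif(4), pc = 0.1), rep(0, 4))
  ip <- c(2, 4, 8)
  expect_equal(fold_enrichment(ip, rep(0, 3), pc = 0.5), ip / 0.5)
  expect_error(fold_enrichment(1:4, 1:5, 1), "different lengths")
})

test_that("low-signal mask removes the sub-threshold cumulative prefix", {
  expect_equal(low_signal_mask(c(1, 2, 3, 94), 0.03),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(low_signal_mask(c(5, 1, 2), 0), rep(FALSE, 3))
  # constant signal: cumulative of k positions is k*c; k*c < 3c holds for
  # k <= 2, so exactly 2 positions masked on length 100 (ties broken by index)
  m <- low_signal_mask(rep(4, 100), 0.03)
  expect_equal(which(m), c(1, 2))
  # zero-coverage positions are always masked when any signal exists
  x <- c(0, 3, 0, 9, 0)
  expect_true(all(low_signal_mask(x, 0.03)[x == 0]))
  expect_equal(low_signal_mask(rep(0, 10), 0.03), rep(FALSE, 10))
})

test_that("rolling average is centered, left-heavy for even windows, and shrinks at edges", {
  x <- c(0, 0, 10, 0, 0)
  expect_equal(rolling_average(x, 1), x)
  expect_equal(rolling_average(x, 5)[3], 2.0)
  expect_equal(rolling_average(rep(3.5, 20), 7), rep(3.5, 20))
  # even window 10 at position i spans [i-4, i+5]
  y <- as.numeric(1:30)
  expect_equal(rolling_average(y, 10)[10], mean(y[6:15]))
  # edge windows shrink to the available positions
  expect_equal(rolling_average(y, 5)[1], mean(y[1:3]))
  expect_equal(rolling_average(y, 5)[30], mean(y[28:30]))
  expect_error(rolling_average(y, 0), "window")
})

test_that("rRNA pipeline masks before smoothing and bounds self-comparison", {
  sim <- simulate_rrna_experiment(
    default_rrna_config(seed = 41, ip_library = 2e4, control_library = 800))
  L <- 1869
  ip <- coverage_from_reads(sim$reads$ip_untreated, L, library_size = 2e4)
  enr <- rrna_enrichment_pipeline(
    ip, coverage_from_reads(sim$reads$trunc_untreated, L, library_size = 800))
  expect_true(all(enr$fold[enr$mask] == 1))
  expect_equal(length(enr$smoothed), L)

  # ip compared against itself: pseudocount strictly deflates the ratio
  self <- rrna_enrichment_pipeline(ip, ip)
  expect_true(all(self$smoothed <= 1 + 1e-12))
})

test_that("fold track is invariant to replicating every read k times", {
  cfg <- default_rrna_config(seed = 13, ip_library = 5000, control_library = 400)
  sim <- simulate_rrna_experiment(cfg)
  L <- 1869
  base <- rrna_enrichment_pipeline(
    coverage_from_reads(sim$reads$ip_untreated, L, library_size = 5000),
    coverage_from_reads(sim$reads$trunc_untreated, L, library_size = 400))
  k <- 3
  rep_reads <- function(r) r[rep(seq_len(nrow(r)), each = k), ]
  scaled <- rrna_enrichment_pipeline(
    coverage_from_reads(rep_reads(sim$reads$ip_untreated), L,
                        library_size = 5000 * k),
    coverage_from_reads(rep_reads(sim$reads$trunc_untreated), L,
                        library_size = 400 * k))
  expect_equal(scaled$fold, base$fold, tolerance = 1e-9)
  expect_equal(scaled$mask, base$mask)
})

test_that("region enrichment grows monotonically with the planted fold", {
  L <- 1869
  means <- vapply(c(1, 2, 3, 5), function(f) {
    cfg <- default_rrna_config(seed = 77, footprint_fold = f,
                               ip_library = 5e4, control_library = 800)
    sim <- simulate_rrna_experiment(cfg)
    enr <- rrna_enrichment_pipeline(
      coverage_from_reads(sim$reads$ip_untreated, L, library_size = 5e4),
      coverage_from_reads(sim$reads$trunc_untreated, L, library_size = 800))
    enr$summary$mean_smoothed[enr$summary$region == "ES7"]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("replicate averaging and track output are well formed", {
  L <- 1869
  tracks <- lapply(c(61, 62), function(s) {
    sim <- simulate_rrna_experiment(
      default_rrna_config(seed = s, ip_library = 2e4, control_library = 600))
    rrna_enrichment_pipeline(
      coverage_from_reads(sim$reads$ip_treated, L, library_size = 2e4),
      coverage_from_reads(sim$reads$trunc_treated, L, library_size = 600))
  })
  avg <- average_enrichment(tracks)
  expect_equal(avg$fold, (tracks[[1]]$fold + tracks[[2]]$fold) / 2)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(tracks[[1]], path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), L)
  expect_equal(tab$fold, tracks[[1]]$fold)
})
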