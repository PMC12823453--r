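test_that("knockout fold track divides by pseudocounted knockout RPM", {
  p <- clip_params()
  # constant tracks: the per-locus low-signal filter masks the first two
  # positions (ties by index); all other positions follow ip/(ko + 5)
  f1 <- ko_fold_track(rep(5, 100), rep(5, 100), p)
  expect_equal(f1[3:100], rep(0.5, 98))
  expect_equal(f1[1:2], c(1, 1))

  f2 <- ko_fold_track(rep(10, 100), rep(0, 100), p)
  expect_equal(f2[3:100], rep(2, 98))

  f3 <- ko_fold_track(rep(0, 50), runif(50, 0, 3), p)
  expect_true(all(f3 %in% c(0, 1)))
  expect_error(ko_fold_track(1:5, 1:4, p), "different lengths")
})

test_that("candidate runs enforce strict fold, length and RPM thresholds", {
  p <- clip_params()
  base_rpm <- rep(20, 200)

  fold <- rep(1, 200); fold[50:74] <- 3  # 25 qualifying positions
  runs <- candidate_runs(fold, base_rpm, p)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$start, runs$end, runs$length), c(50, 74, 25))

  fold20 <- rep(1, 200); fold20[50:69] <- 3  # exactly 20: rejected
  expect_equal(nrow(candidate_runs(fold20, base_rpm, p)), 0)

  expect_equal(nrow(candidate_runs(rep(2, 200), base_rpm, p)), 0)  # fold == 2

  # mean RPM must strictly exceed 10
  runs_lo <- candidate_runs(fold, rep(10, 200), p)
  expect_equal(nrow(runs_lo), 0)
  runs_hi <- candidate_runs(fold, rep(10 + 1e-9, 200), p)
  expect_equal(nrow(runs_hi), 1)
})

test_that("one-sided Poisson tail matches hand-derived values and the pmf oracle", {
  expect_equal(poisson_upper_p(0, 0.5), 1)
  expect_equal(poisson_upper_p(0, 100), 1)
  expect_equal(poisson_upper_p(5, 1), 0.003660, tolerance = 1e-4)
  expect_equal(poisson_upper_p(2, 2), 1 - 3 * exp(-2))
  expect_error(poisson_upper_p(3, 0), "lambda")
  expect_error(poisson_upper_p(-1, 2), "non-negative")

  for (lambda in c(0.1, 2, 10)) {
    for (obs in c(0:5, 20, 60)) {
      expect_equal(poisson_upper_p(obs, lambda),
                   brute_poisson_upper(obs, lambda), tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment reproduces the hand step-up in input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, hand_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("peak statistics count overlapping reads with a pseudocounted expectation", {
  p <- clip_params()
  run <- data.frame(start = 101, end = 140)
  none <- make_reads(integer(0), 20)
  st0 <- peak_statistics(run, none, none, ip_lib = 1e5, ko_lib = 5e4, p)
  expect_equal(st0$observed, 0L)
  expect_equal(st0$lambda, 5 * 2)
  expect_equal(poisson_upper_p(st0$observed, st0$lambda), 1)

  ip <- make_reads(c(85, 100, 120, 139, 140, 300), 20)   # 0-based starts
  ko <- make_reads(c(90, 200), 20)
  st <- peak_statistics(run, ip, ko, ip_lib = 1e5, ko_lib = 1e5, p)
  # run is [100, 140) in 0-based terms: read at 85 spans [85,105) -> overlaps;
  # 140 spans [140,160) -> outside; 300 outside
  expect_equal(st$observed, 4L)
  expect_equal(st$lambda, (1 + 5) * 1)

  st2 <- peak_statistics(run, ip, ko, ip_lib = 2e5, ko_lib = 2e5, p)
  expect_equal(st2$lambda, st$lambda)  # library-ratio invariance
  expect_error(peak_statistics(run, ip, ko, 1e5, 0, p), "knockout library")

  stc <- peak_statistics(run, ip, ko, 1e5, 1e5, p, count_mode = "coverage",
                         reference_length = 400)
  expect_gt(stc$observed, st$observed)  # coverage sums exceed read counts
})

test_that("planted transcript footprints are recovered as significant peaks", {
  cfg <- sim_config(two_cond_samples(), c(ip_u = 1e5, ip_t = 1e5, ko = 1e5),
                    seed = 42)
  tsim <- simulate_transcriptome_experiment(
    cfg, n_genes = 6,
    footprints = list(transcript_footprint(1, fold = 4, width = 40)))
  peaks <- call_peaks(sim_samples(tsim), tsim$annotation)
  truth <- tsim$truth$footprints
  for (cond in c("untreated", "treated")) {
    pk <- peaks[peaks$condition == cond, ]
    expect_equal(nrow(pk), 1)
    expect_equal(pk$locus, truth$transcript_id)
    expect_true(pk$qvalue < 0.05)
    expect_gte(interval_jaccard(pk$start, pk$end, truth$start, truth$end), 0.6)
  }
  # reported peaks satisfy the type invariants
  expect_true(all(peaks$length >= 21))
  expect_true(all(peaks$mean_fold > 2))
  expect_true(all(peaks$mean_rpm > 10))
  expect_true(all(peaks$qvalue >= peaks$pvalue))
})

test_that("non-canonical decoys and missing knockouts are handled", {
  cfg <- sim_config(two_cond_samples(), c(ip_u = 8e4, ip_t = 8e4, ko = 8e4),
                    seed = 5)
  tsim <- simulate_transcriptome_experiment(
    cfg, n_genes = 3, decoys_per_gene = 1,
    footprints = list(transcript_footprint(1, fold = 5, width = 50)))
  peaks <- call_peaks(sim_samples(tsim), tsim$annotation)
  expect_true(all(peaks$locus %in%
                    tsim$annotation$transcript_id[tsim$annotation$canonical == 1]))
  expect_false(any(grepl("\\.d1$", peaks$locus)))

  no_ko <- Filter(function(s) s$role != "knockout", sim_samples(tsim))
  expect_error(call_peaks(no_ko, tsim$annotation), "knockout")
})

test_that("translating all reads translates every called peak", {
  L <- 600
  k <- 7
  ip_starts <- c(rep(200:249, each = 8), seq(0, 500, by = 10))
  ko_starts <- seq(5, 500, by = 25)
  ann <- one_tx_annotation(100, 400, 100)
  mk <- function(shift) {
    list(
      list(name = "ip", role = "ip", condition = "untreated",
           reads = make_reads(ip_starts + shift, 20, "tx", L),
           library_size = 5000),
      list(name = "ko", role = "knockout", condition = "untreated",
           reads = make_reads(ko_starts + shift, 20, "tx", L),
           library_size = 5000))
  }
  p0 <- call_peaks(mk(0), ann)
  p1 <- call_peaks(mk(k), ann)
  expect_gt(nrow(p0), 0)
  expect_equal(p1$start, p0$start + k)
  expect_equal(p1$end, p0$end + k)
  expect_equal(p1$pvalue, p0$pvalue)
})
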