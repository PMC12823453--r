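test_that("identical config and seed reproduce byte-identical output", {
  cfg <- default_rrna_config(seed = 99, ip_library = 5000, control_library = 500)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_rrna_experiment(cfg), d1)
  write_simulation(simulate_rrna_experiment(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the reads
  cfg2 <- default_rrna_config(seed = 100, ip_library = 5000, control_library = 500)
  sim2 <- simulate_rrna_experiment(cfg2)
  sim1 <- simulate_rrna_experiment(cfg)
  expect_false(identical(sim1$reads$ip_untreated, sim2$reads$ip_untreated))
})

test_that("multinomial allocation makes library sizes exact", {
  cfg <- default_rrna_config(seed = 3, ip_library = 12345, control_library = 678)
  sim <- simulate_rrna_experiment(cfg)
  for (nm in names(sim$reads)) {
    expect_equal(nrow(sim$reads[[nm]]), cfg$library_sizes[[nm]], label = nm)
  }
  # expected start rates in the truth record sum to the library size
  for (nm in names(sim$truth$expected_start_rates)) {
    expect_equal(sum(sim$truth$expected_start_rates[[nm]]),
                 cfg$library_sizes[[nm]])
  }
})

test_that("invalid simulation inputs are rejected by name", {
  samples <- ip_ko_samples()
  libs <- c(ip = 100, ko = 100)
  expect_error(
    simulate_rrna_experiment(
      sim_config(samples, libs, reference_length = 500,
                 footprints = list(footprint(400, 600, 2, name = "oops")))),
    "oops")
  expect_error(sim_config(samples, libs, background_rate = -1), ">= 0")
  expect_error(footprint(10, 20, fold = -0.5), ">= 0")
  expect_error(footprint(20, 10, fold = 1), "start <= end")
  expect_error(sim_config(samples, c(ip = 100), seed = 1),
               "every sample")
})

test_that("a footprint-free configuration yields flat coverage", {
  cfg <- sim_config(ip_ko_samples(), c(ip = 1e5, ko = 100), seed = 17,
                    reference_length = 1869)
  sim <- simulate_rrna_experiment(cfg)
  starts <- sim$reads$ip$start + 1L
  counts <- tabulate(starts, nbins = 1869)
  gof <- suppressWarnings(chisq.test(counts, p = rep(1 / 1869, 1869)))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted footprints are recovered at the configured fold", {
  W <- 1195 - 1117 + 1
  L <- 1869
  ratios <- numeric(30)
  ctl_ratios <- numeric(30)
  for (i in seq_len(30)) {
    cfg <- sim_config(
      data.frame(name = c("ip", "ct"), role = c("ip", "truncation_control"),
                 condition = "untreated"),
      c(ip = 2e4, ct = 2e4),
      footprints = list(footprint(1117, 1195, 3)),
      seed = 1000 + i)
    sim <- simulate_rrna_experiment(cfg)
    rate_ratio <- function(reads) {
      s <- reads$start + 1L
      inside <- sum(s >= 1117 & s <= 1195)
      outside <- length(s) - inside
      (inside / W) / (outside / (L - W))
    }
    ratios[i] <- rate_ratio(sim$reads$ip)
    ctl_ratios[i] <- rate_ratio(sim$reads$ct)
  }
  # start-rate ratio: within 5% of the configured fold, and the Monte-Carlo
  # mean within 3 standard errors
  expect_lt(abs(mean(ratios) - 3), 0.15)
  expect_lt(abs(mean(ratios) - 3), 3 * sd(ratios) / sqrt(30) + 1e-9 + 0.02)
  expect_lt(abs(mean(ctl_ratios) - 1), 0.05)
})

test_that("simulated coverage matches the exact expected-coverage oracle", {
  # depth (full-read-span) coverage dilutes the footprint edges, so the
  # coverage-ratio expectation is computed from the truth rates, not
  # assumed equal to the planted start-rate fold
  cfg <- sim_config(
    data.frame(name = "ip", role = "ip", condition = "untreated"),
    c(ip = 5e4), footprints = list(footprint(1117, 1195, 3)), seed = 55)
  inside <- 1117:1195
  exp_cov <- expected_coverage_from_starts(
    simulate_rrna_experiment(cfg)$truth$expected_start_rates$ip,
    cfg$read_length)
  exp_ratio <- mean(exp_cov[inside]) / mean(exp_cov[-inside])
  expect_gt(exp_ratio, 2.5)  # strong enrichment survives edge dilution
  expect_lt(exp_ratio, 3)

  obs <- numeric(25)
  for (i in seq_len(25)) {
    cfg_i <- sim_config(
      data.frame(name = "ip", role = "ip", condition = "untreated"),
      c(ip = 5e4), footprints = list(footprint(1117, 1195, 3)),
      seed = 2000 + i)
    cov <- coverage_from_reads(simulate_rrna_experiment(cfg_i)$reads$ip, 1869)
    obs[i] <- mean(cov$counts[inside]) / mean(cov$counts[-inside])
  }
  expect_lt(abs(mean(obs) - exp_ratio),
            3 * sd(obs) / sqrt(25) + 0.01)
})

test_that("transcriptome simulation emits valid annotations and reads", {
  cfg <- sim_config(two_cond_samples(), c(ip_u = 2e4, ip_t = 2e4, ko = 2e4),
                    seed = 7)
  sim <- simulate_transcriptome_experiment(
    cfg, n_genes = 4, decoys_per_gene = 1,
    footprints = list(transcript_footprint(2, fold = 4, width = 40,
                                           conditions = "treated")))
  ann <- sim$annotation
  expect_equal(sum(ann$canonical == 1), 4)
  expect_equal(sum(ann$canonical == 0), 4)
  expect_equal(anyDuplicated(ann$transcript_id), 0)
  # every read fits inside its transcript
  lens <- setNames(ann$len_5utr + ann$len_cds + ann$len_3utr, ann$transcript_id)
  for (nm in names(sim$reads)) {
    r <- sim$reads[[nm]]
    expect_true(all(r$start >= 0))
    expect_true(all(r$end <= lens[r$reference]))
    expect_equal(nrow(r), cfg$library_sizes[[nm]])
  }
  # the treated-only footprint enriches only the treated IP rates
  fp <- sim$truth$footprints
  expect_equal(fp$transcript_id, "t002")
  expect_equal(fp$end - fp$start + 1L, 40L)

  expect_error(
    simulate_transcriptome_experiment(
      cfg, n_genes = 2,
      length_sampler = function(n) data.frame(len_5utr = 10, len_cds = 0,
                                              len_3utr = 10)),
    "CDS length")
  expect_error(
    simulate_transcriptome_experiment(
      cfg, n_genes = 2,
      footprints = list(transcript_footprint(5, fold = 2))),
    "gene index")
})
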