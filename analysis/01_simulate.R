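#!/usr/bin/env Rscript

# Step 1 — generate the synthetic experiments used by the downstream
# analyses: an rRNA CLIP experiment with footprints planted at the two 18S
# expansion-segment regions (ES7 1117-1195 in both conditions, ES6b/c
# 710-766 only under treatment), and a transcript-locus experiment with one
# fourfold CDS footprint. Reads, truth records and manifests land under
# results/sim_*.

library(clipfold)

seed <- 1L

rsim <- simulate_rrna_experiment(default_rrna_config(seed = seed))
write_simulation(rsim, "results/sim_rrna")
cat("rRNA simulation:", sum(sapply(rsim$reads, nrow)), "reads across",
    length(rsim$reads), "samples; planted footprints:\n")
print(rsim$truth$footprints)

samples <- data.frame(
  name = c("ip_untreated", "ip_treated", "ko"),
  role = c("ip", "ip", "knockout"),
  condition = c("untreated", "treated", "untreated"))
tcfg <- sim_config(samples,
                   c(ip_untreated = 2e5, ip_treated = 2e5, ko = 2e5),
                   seed = seed + 1L)
tsim <- simulate_transcriptome_experiment(
  tcfg, n_genes = 8,
  footprints = list(transcript_footprint(1, fold = 4, width = 40)))
write_simulation(tsim, "results/sim_transcripts")
cat("\ntranscript simulation:", nrow(tsim$annotation), "transcripts;",
    "planted footprint:\n")
print(tsim$truth$footprints)
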