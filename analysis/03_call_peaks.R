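#!/usr/bin/env Rscript

# Step 3 — knockout-normalized peak calling (stage 2).
# Calls per-transcript peaks on the simulated transcript loci: runs of more
# than 20 consecutive positions exceeding twofold over the pseudocounted
# knockout, mean RPM above 10, one-sided Poisson test on overlapping read
# counts, BH-adjusted per condition. The planted fourfold footprint on t001
# should be the only significant peak in each condition.

library(clipfold)

manifest <- read_manifest("results/sim_transcripts/manifest.tsv")
manifest$path <- file.path("results/sim_transcripts", manifest$path)
annotation <- read_annotation("results/sim_transcripts/annotation.tsv")

samples <- lapply(seq_len(nrow(manifest)), function(i) {
  m <- manifest[i, ]
  list(name = m$sample, role = m$role, condition = m$condition,
       reads = read_intervals(m$path, "BED"),
       library_size = m$library_size)
})

peaks <- call_peaks(samples, annotation)
write_peaks(peaks, "results/peaks.tsv", bed = "results/peaks.bed")
cat("significant peaks (q < 0.05):\n")
print(peaks[, c("condition", "locus", "start", "end", "length", "mean_fold",
                "mean_rpm", "observed", "lambda", "qvalue")])

truth <- jsonlite::read_json("results/sim_transcripts/truth.json",
                             simplifyVector = TRUE)$footprints
cat("\nplanted truth interval:", truth$transcript_id,
    paste0(truth$start, "-", truth$end), "fold", truth$fold, "\n")
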