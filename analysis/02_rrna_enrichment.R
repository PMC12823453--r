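#!/usr/bin/env Rscript

# Step 2 — truncation-normalized 18S enrichment tracks (stage 1).
# Reads the simulated samples from results/sim_rrna, builds the smoothed
# fold-enrichment track per condition and summarizes the two
# expansion-segment regions. Expect ES7 above the twofold line in both
# conditions and ES6b/c only under treatment.

library(clipfold)

dir.create("results", showWarnings = FALSE)
manifest <- read_manifest("results/sim_rrna/manifest.tsv")
manifest$path <- file.path("results/sim_rrna", manifest$path)
L <- 1869L

for (cond in unique(manifest$condition[manifest$role == "ip"])) {
  ip_row <- manifest[manifest$role == "ip" & manifest$condition == cond, ][1, ]
  ct_row <- manifest[manifest$role == "truncation_control" &
                       manifest$condition == cond, ][1, ]
  ip <- coverage_from_reads(read_intervals(ip_row$path, "BED", L), L,
                            library_size = ip_row$library_size)
  ct <- coverage_from_reads(read_intervals(ct_row$path, "BED", L), L,
                            library_size = ct_row$library_size)
  enr <- rrna_enrichment_pipeline(ip, ct)
  write_enrichment(enr, sprintf("results/enrichment_%s.tsv", cond),
                   bedgraph = sprintf("results/enrichment_%s.bedGraph", cond))
  write.table(enr$summary, sprintf("results/enrichment_%s_regions.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\n==", cond, "(pseudocount", signif(enr$pseudocount, 3), ")\n")
  print(enr$summary)
}
cat("\nTracks and per-region summaries written under results/.\n")
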