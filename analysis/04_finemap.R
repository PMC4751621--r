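#!/usr/bin/env Rscript

# Stage 4: fine mapping.
#
# The top windows of the 100-SNP scan (ranked by LRT) are re-scanned with
# 10-SNP windows at 5-SNP overlap to localize the signal; the genome scan's
# null fit is reused.

library(rhmscan)

gm <- read_plink("results/data/cohort_qc")
ph <- read.table("results/phenotype.tsv", header = TRUE, sep = "\t")
y <- setNames(ph$y, ph$sample_id)
G_w <- read_grm("results/whole_genome")
scan <- readRDS("results/rhm_scan100.rds")

k <- min(10, nrow(scan$results))  # scaled version of a top-100 follow-up
fine <- fine_map_scan(scan, y, gm, G_w, k = k, size = 10, stride = 5)

write.table(format_scan_results(fine), "results/rhm_fine10.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

thr <- threshold_set("window10", nrow(fine$results))
print(thr)

top <- fine$results[order(-fine$results$LRT), ][1:5, ]
message("Top five fine windows:")
print(top[, c("window_id", "parent_window_id", "chromosome", "bp_start",
              "bp_end", "LRT", "neg_log10_p", "h2_region")],
      row.names = FALSE)
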