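#!/usr/bin/env Rscript

# Stage 5: the single-SNP mixed-model scan (the comparison method).
#
# One polygenic REML null fit with the whole-genome kinship as a random
# effect, then a score test per SNP against a one-degree chi-square.

library(rhmscan)

gm <- read_plink("results/data/cohort_qc")
ph <- read.table("results/phenotype.tsv", header = TRUE, sep = "\t")
y <- setNames(ph$y, ph$sample_id)
G_w <- read_grm("results/whole_genome")

null_fit <- fit_polygenic_null(y, G_w)
print(null_fit)

res <- scan_snps(null_fit, gm)
write.table(res, "results/ssgwas.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

thr <- threshold_set("ssgwas", sum(res$flag == "ok"))
print(thr)

top <- res[order(-res$stat), ][1:5, ]
message("Top five SNPs:")
print(top, row.names = FALSE)
message(sum(res$neg_log10_p >= thr$genomewide, na.rm = TRUE),
        " SNPs at the genome-wide threshold, ",
        sum(res$neg_log10_p >= thr$suggestive, na.rm = TRUE),
        " at the suggestive threshold")
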