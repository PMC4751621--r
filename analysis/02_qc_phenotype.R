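#!/usr/bin/env Rscript

# Stage 2: genotype quality control and phenotype preparation.
#
# Discards SNPs with MAF < 0.001, exact-test HWE p < 1e-8 or call rate
# < 0.98, then individuals with call rate < 0.98; adjusts the trait for
# sex, age and age^2 within each cohort and rank-transforms the residuals
# to the standard normal. The adjusted, rank-transformed values are the
# phenotype for both scans.

library(rhmscan)

gm <- read_plink("results/data/cohort")
print(gm)

qc <- apply_qc(gm, qc_thresholds())
print(qc$report)

pheno <- read.table("results/data/cohort.pheno.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
common <- intersect(qc$genotypes$samples, pheno$sample_id)
prep <- prepare_phenotype(pheno[pheno$sample_id %in% common, ])
gm_qc <- subset_genotypes(qc$genotypes,
                          samples = match(names(prep$values),
                                          qc$genotypes$samples))

dir.create("results", showWarnings = FALSE)
write.table(data.frame(sample_id = names(prep$values), y = prep$values),
            "results/phenotype.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_plink(gm_qc, "results/data/cohort_qc")

G_w <- bend_psd(genomic_relationship(gm_qc, role = "whole_genome"))
print(G_w)
write_grm(G_w, "results/whole_genome")

message("QC left ", length(gm_qc$samples), " individuals and ",
        nrow(gm_qc$variants), " SNPs; whole-genome GRM written in GCTA ",
        "format to results/whole_genome.grm.gz")
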