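#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# A merged set of three family-structured cohorts (n = 1,000 here, a scaled
# version of a ~2,250-adult field study) typed on a 2,500-SNP map of five
# chromosomes, with one 100-SNP region on chromosome 3 contributing 10% of
# trait variance through ten causal SNPs, on a 45% polygenic background,
# with sex/age/age^2 covariate effects, sporadic missing calls and ten
# assay-failure SNPs that violate Hardy-Weinberg equilibrium. (At this
# reduced sample size a regional signal of a few percent sits at the edge
# of detectability — single-window sampling error is of the same order —
# so the demonstration region is made proportionally stronger.)

library(rhmscan)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_samples = 1000, n_cohorts = 3, n_families = 150, sibship_size = 3,
  n_chromosomes = 5, snps_per_chromosome = 500,
  qtl_spec = list(list(chromosome = 3, window = 201:300, h2_region = 0.10,
                       n_causal = 10, causal_maf_class = "common")),
  h2_poly = 0.45, missing_rate = 0.005, n_hwe_violators = 10, seed = 20260920)

coh <- simulate_cohort(cfg)
print(coh)
write_cohort(coh, file.path(out_dir, "cohort"))

message("Simulated ", nrow(coh$phenotype), " individuals, ",
        nrow(coh$genotypes$variants), " SNPs.")
message("Realized variance fractions: regional ",
        sprintf("%.3f", coh$truth$h2_region_realized), ", polygenic ",
        sprintf("%.3f", coh$truth$h2_poly_realized), ".")
message("Causal SNPs: ", paste(coh$truth$causal_snp_ids, collapse = ", "))
message("Wrote PLINK triplet, phenotype TSV and truth JSON under ", out_dir)
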