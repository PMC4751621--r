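# shared fixtures, built in code at test time

# 4 samples x 5 SNPs; SNP s3 monomorphic, sample id2 missing 3 of 5 calls
toy_genotypes <- function() {
  vals <- rbind(
    id1 = c(0,   0.5, 0, 1,   0.5),
    id2 = c(NA,  NA,  0, NA,  1),
    id3 = c(0.5, 1,   0, 0.5, 0),
    id4 = c(1,   0,   0, 0,   0.5))
  genotype_matrix(
    vals,
    variants = data.frame(snp_id = paste0("s", 1:5), chromosome = 1L,
                          position = as.integer(1:5 * 1000),
                          allele_a = "A", allele_b = "B"),
    samples = rownames(vals))
}

# small related cohort reused across tests (one simulation per test run)
small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(small_cohort_cache$coh)) {
    cfg <- sim_config(n_samples = 300, n_families = 45, sibship_size = 3,
                      n_chromosomes = 2, snps_per_chromosome = 500,
                      qtl_spec = list(list(chromosome = 1, window = 201:300,
                                           h2_region = 0.25, n_causal = 10,
                                           causal_maf_class = "common")),
                      h2_poly = 0.45, seed = 424242)
    small_cohort_cache$coh <- simulate_cohort(cfg)
  }
  small_cohort_cache$coh
}

# post-QC genotypes + prepared phenotype + whole-genome GRM for the small
# cohort, aligned
small_analysis <- function() {
  if (is.null(small_cohort_cache$ana)) {
    coh <- small_cohort()
    qc <- apply_qc(coh$genotypes)
    y <- prepare_phenotype(coh$phenotype)$values
    ids <- intersect(names(y), qc$genotypes$samples)
    gm <- subset_genotypes(qc$genotypes,
                           samples = match(ids, qc$genotypes$samples))
    y <- y[gm$samples]
    G_w <- bend_psd(genomic_relationship(gm))
    small_cohort_cache$ana <- list(coh = coh, gm = gm, y = y, G_w = G_w)
  }
  small_cohort_cache$ana
}

# windows of a scan that overlap the simulated QTL's causal positions
harboring_windows <- function(results, truth) {
  cp <- range(truth$causal_positions)
  chr <- truth$causal_chromosomes[1]
  which(results$chromosome == chr & results$bp_end >= cp[1] &
          results$bp_start <= cp[2])
}
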