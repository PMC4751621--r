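one_snp_gm <- function(dosages) {
  genotype_matrix(matrix(dosages, length(dosages), 1),
                  data.frame(snp_id = "s1", chromosome = 1L, position = 1L,
                             allele_a = "A", allele_b = "B"),
                  paste0("i", seq_along(dosages)))
}

test_that("single-SNP off-diagonal follows the frequency-weighted product", {
  # p = 0.5; individuals BB (g=1) and AA (g=0):
  # f_12 = 2 * (0.5)(-0.5) / 0.25 = -2
  G <- genomic_relationship(one_snp_gm(c(1, 0)))
  expect_equal(G$values[1, 2], -2)
  expect_equal(G$values[2, 1], -2)
})

test_that("outbred HWE sample has unit diagonal and null off-diagonal", {
  cfg <- sim_config(n_samples = 200, n_families = 0, sibship_size = 0,
                    n_chromosomes = 2, snps_per_chromosome = 1000,
                    ld_decay = 0, qtl_spec = list(), h2_poly = 0.3,
                    missing_rate = 0, n_hwe_violators = 0, seed = 5)
  gm <- simulate_genotypes(cfg)
  G <- genomic_relationship(gm)
  off <- G$values[upper.tri(G$values)]
  expect_gt(mean(diag(G$values)), 0.95)
  expect_lt(mean(diag(G$values)), 1.05)
  expect_gt(mean(off), -0.02)
  expect_lt(mean(off), 0.02)
})

test_that("full sibs average 0.5 relatedness; families exceed non-families", {
  cfg <- sim_config(n_samples = 200, n_families = 30, sibship_size = 3,
                    n_chromosomes = 2, snps_per_chromosome = 1200,
                    qtl_spec = list(), h2_poly = 0.3, missing_rate = 0,
                    n_hwe_violators = 0, seed = 6)
  gm <- simulate_genotypes(cfg)
  reg <- attr(gm, "registry")
  G <- genomic_relationship(gm)$values
  sib_pairs <- within_fam <- between <- c()
  for (i in 1:(nrow(reg) - 1)) for (j in (i + 1):nrow(reg)) {
    same <- !is.na(reg$family_id[i]) && !is.na(reg$family_id[j]) &&
      reg$family_id[i] == reg$family_id[j]
    if (same) {
      within_fam <- c(within_fam, G[i, j])
      if (reg$role[i] == "offspring" && reg$role[j] == "offspring")
        sib_pairs <- c(sib_pairs, G[i, j])
    } else between <- c(between, G[i, j])
  }
  expect_gt(mean(sib_pairs), 0.45)
  expect_lt(mean(sib_pairs), 0.55)
  expect_gt(mean(within_fam), mean(between))
})

test_that("disjoint SNP sets combine as the m-weighted off-diagonal mean", {
  coh <- small_cohort()
  gm <- subset_genotypes(coh$genotypes, samples = 1:40, snps = 1:60)
  gm$values[is.na(gm$values)] <- 0.5  # no-missingness premise
  gm <- genotype_matrix(gm$values, gm$variants, gm$samples)
  s1 <- 1:25
  s2 <- 26:60
  G1 <- suppressWarnings(genomic_relationship(gm, s1))
  G2 <- suppressWarnings(genomic_relationship(gm, s2))
  G12 <- suppressWarnings(genomic_relationship(gm, c(s1, s2)))
  m1 <- G1$m; m2 <- G2$m
  lhs <- G12$values
  rhs <- (m1 * G1$values + m2 * G2$values) / (m1 + m2)
  off <- upper.tri(lhs)
  expect_equal(lhs[off], rhs[off], tolerance = 1e-12)
})

test_that("relationships are invariant to A/B allele relabeling", {
  coh <- small_cohort()
  gm <- subset_genotypes(coh$genotypes, samples = 1:50, snps = 1:40)
  G <- suppressWarnings(genomic_relationship(gm))
  flipped <- gm
  flip <- c(3, 7, 20)
  flipped$values[, flip] <- 1 - flipped$values[, flip]
  G2 <- suppressWarnings(genomic_relationship(flipped))
  expect_equal(G2$values, G$values, tolerance = 1e-12)
})

test_that("bend_psd floors negative eigenvalues and passes PSD untouched", {
  I5 <- diag(5)
  expect_identical(bend_psd(I5), I5)
  # symmetric matrix with a controlled negative eigenvalue
  Q <- qr.Q(qr(matrix(stats::rnorm(25), 5)))
  A <- Q %*% diag(c(2, 1, 0.5, 0.1, -0.01)) %*% t(Q)
  A <- (A + t(A)) / 2
  B <- bend_psd(A, floor = 1e-6)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 1e-6, tolerance = 1e-9)
  expect_identical(bend_psd(B + diag(1e-3, 5)), B + diag(1e-3, 5))
})

test_that("GCTA text format round-trips the matrix and pair counts", {
  coh <- small_cohort()
  gm <- subset_genotypes(coh$genotypes, samples = 1:30, snps = 1:100)
  G <- suppressWarnings(genomic_relationship(gm))
  prefix <- file.path(tempdir(), "grm_rt")
  write_grm(G, prefix)
  back <- read_grm(prefix)
  expect_equal(back$values, G$values, tolerance = 1e-9)
  expect_equal(back$m_pairs, G$m_pairs)
  expect_identical(back$sample_ids, G$sample_ids)
})
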