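test_that("config invariants are enforced", {
  expect_error(sim_config(h2_poly = 0.9,
                          qtl_spec = list(list(chromosome = 1,
                                               window = 1:10,
                                               h2_region = 0.2,
                                               n_causal = 2,
                                               causal_maf_class = "common"))),
               "must be < 1")
  expect_error(sim_config(n_samples = 10, n_families = 5, sibship_size = 3),
               "families need")
  expect_error(sim_config(qtl_spec = list(list(chromosome = 30,
                                               window = 1:10,
                                               h2_region = 0.1,
                                               n_causal = 1,
                                               causal_maf_class = "common"))),
               "outside the simulated map")
  expect_error(sim_config(ld_decay = 1.2), "fractions")
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_samples = 80, n_families = 10, sibship_size = 2,
                    n_chromosomes = 1, snps_per_chromosome = 100,
                    qtl_spec = list(list(chromosome = 1, window = 41:60,
                                         h2_region = 0.1, n_causal = 3,
                                         causal_maf_class = "common")),
                    h2_poly = 0.3, seed = 12345)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$phenotype$trait, b$phenotype$trait)
  expect_identical(a$truth, b$truth)
})

test_that("independent unrelated genotypes satisfy HWE", {
  cfg <- sim_config(n_samples = 500, n_families = 0, sibship_size = 0,
                    n_chromosomes = 1, snps_per_chromosome = 200,
                    ld_decay = 0, qtl_spec = list(), h2_poly = 0.2,
                    missing_rate = 0, n_hwe_violators = 0, seed = 8)
  gm <- simulate_genotypes(cfg)
  # chi-square goodness of fit against p^2 : 2pq : q^2 per SNP,
  # Bonferroni over 200 SNPs at alpha = 0.01
  pvals <- vapply(seq_len(200), function(k) {
    g <- gm$values[, k]
    p <- mean(g)
    if (p == 0 || p == 1) return(1)
    obs <- c(sum(g == 0), sum(g == 0.5), sum(g == 1))
    expc <- 500 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    keep <- expc > 0
    stat <- sum((obs[keep] - expc[keep])^2 / expc[keep])
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(pvals > 0.01 / 200))
})

test_that("adjacent-marker LD appears with copying and not without", {
  base <- list(n_samples = 400, n_families = 0, sibship_size = 0,
               n_chromosomes = 1, snps_per_chromosome = 150,
               qtl_spec = list(), h2_poly = 0.2, missing_rate = 0,
               n_hwe_violators = 0, seed = 13)
  ld_r2 <- function(ld) {
    cfg <- do.call(sim_config, c(base, list(ld_decay = ld)))
    gm <- simulate_genotypes(cfg)
    v <- gm$values
    mean(vapply(1:149, function(k) {
      if (stats::sd(v[, k]) == 0 || stats::sd(v[, k + 1]) == 0) return(0)
      stats::cor(v[, k], v[, k + 1])^2
    }, numeric(1)))
  }
  expect_lt(ld_r2(0), 0.02)
  expect_gt(ld_r2(0.9), 0.2)
})

test_that("realized variance fractions track the nominal targets", {
  h2r <- h2p <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(n_samples = 2000, n_families = 300, sibship_size = 3,
                      n_chromosomes = 4, snps_per_chromosome = 500,
                      qtl_spec = list(list(chromosome = 1, window = 201:300,
                                           h2_region = 0.05, n_causal = 5,
                                           causal_maf_class = "common")),
                      h2_poly = 0.45, seed = 5000 + s)
    coh <- simulate_cohort(cfg)
    h2r[s] <- coh$truth$h2_region_realized
    h2p[s] <- coh$truth$h2_poly_realized
  }
  expect_true(all(abs(h2r - 0.05) < 0.02))
  expect_true(all(abs(h2p - 0.45) < 0.02))
})

test_that("null architecture leaves only covariates plus unit residual", {
  cfg <- sim_config(n_samples = 1000, n_families = 100, sibship_size = 2,
                    n_chromosomes = 1, snps_per_chromosome = 100,
                    qtl_spec = list(), h2_poly = 0, seed = 17)
  coh <- simulate_cohort(cfg)
  B <- coh$truth$covariate_effects
  ph <- coh$phenotype
  ci <- match(ph$cohort, unique(ph$cohort))
  covar <- B[ci, "sex"] * ph$sex + B[ci, "age"] * ph$age +
    B[ci, "age2"] * ph$age^2
  expect_equal(stats::var(ph$trait - covar), 1, tolerance = 1e-8)
})

test_that("distinct per-cohort covariate effects are recoverable", {
  B <- rbind(c(sex = 0.5, age = 0.05, age2 = -4e-4),
             c(sex = -0.2, age = -0.03, age2 = 6e-4))
  cfg <- sim_config(n_samples = 1200, n_cohorts = 2, n_families = 0,
                    sibship_size = 0, n_chromosomes = 1,
                    snps_per_chromosome = 100, qtl_spec = list(),
                    h2_poly = 0.1, covariate_effects = B, seed = 19)
  coh <- simulate_cohort(cfg)
  ph <- coh$phenotype
  for (ci in 1:2) {
    sub <- ph[ph$cohort == paste0("cohort", ci), ]
    fit <- stats::lm(trait ~ sex + age + I(age^2), sub)
    se <- summary(fit)$coefficients[-1, 2]
    expect_true(all(abs(coef(fit)[-1] - B[ci, ]) < 4 * se))
  }
})

test_that("a QTL window with no polymorphic SNP is a named error", {
  cfg <- sim_config(n_samples = 60, n_families = 0, sibship_size = 0,
                    n_chromosomes = 1, snps_per_chromosome = 50,
                    qtl_spec = list(list(chromosome = 1, window = 11:20,
                                         h2_region = 0.1, n_causal = 2,
                                         causal_maf_class = "common")),
                    h2_poly = 0.2, missing_rate = 0, n_hwe_violators = 0,
                    seed = 23)
  gm <- simulate_genotypes(cfg)
  cv <- attr(gm, "complete_values")
  cv[, 11:20] <- 0  # kill the window
  gm$values[, 11:20] <- 0
  attr(gm, "complete_values") <- cv
  expect_error(simulate_phenotypes(gm, config = cfg),
               "no polymorphic SNP")
})

test_that("dropping causal SNPs removes them from the emitted data only", {
  args <- list(n_samples = 150, n_families = 20, sibship_size = 2,
               n_chromosomes = 1, snps_per_chromosome = 200,
               qtl_spec = list(list(chromosome = 1, window = 51:150,
                                    h2_region = 0.1, n_causal = 5,
                                    causal_maf_class = "common")),
               h2_poly = 0.3, seed = 29)
  cfg0 <- do.call(sim_config, args)
  cfg1 <- do.call(sim_config, c(args, list(drop_causal_snps = TRUE)))
  keep <- simulate_cohort(cfg0)
  drop <- simulate_cohort(cfg1)
  expect_identical(drop$phenotype$trait, keep$phenotype$trait)
  expect_true(all(drop$truth$causal_snp_ids %in%
                    keep$genotypes$variants$snp_id))
  expect_false(any(drop$truth$causal_snp_ids %in%
                     drop$genotypes$variants$snp_id))
  expect_equal(nrow(drop$genotypes$variants),
               nrow(keep$genotypes$variants) - 5L)
})

test_that("cohort files round-trip through disk", {
  coh <- small_cohort()
  prefix <- file.path(tempdir(), "cohort_out")
  write_cohort(coh, prefix)
  gm <- read_plink(prefix)
  expect_identical(gm$values, coh$genotypes$values)
  ph <- utils::read.table(paste0(prefix, ".pheno.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  expect_equal(ph$trait, coh$phenotype$trait, tolerance = 1e-12)
  truth <- jsonlite::read_json(paste0(prefix, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$h2_poly_realized, coh$truth$h2_poly_realized,
               tolerance = 1e-9)
})
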