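#' Configuration for the synthetic cohort generator
#'
#' Defines a related genotype cohort with a regional QTL, a polygenic
#' background, covariate effects and array-style artefacts (missing calls,
#' Hardy-Weinberg violating SNPs). Defaults emulate a merged set of three
#' family-structured population cohorts of 2,246 adults typed on a SNP
#' array, with one 100-SNP region contributing a few percent of trait
#' variance on top of a polygenic heritability of 0.45.
#'
#' Genotypes are generated as founder haplotypes with first-order copying
#' LD (a latent uniform shared between adjacent markers with probability
#' \code{ld_decay}, so marginal frequencies follow \code{maf_law} exactly
#' while neighbouring markers are positively correlated) and gene-dropping
#' through two-parent families with recombination between adjacent SNPs.
#'
#' @param n_samples total individuals.
#' @param n_cohorts number of population cohorts (families never straddle
#'   cohorts).
#' @param n_families number of two-parent families; remaining samples are
#'   unrelated singletons.
#' @param sibship_size full sibs per family.
#' @param n_chromosomes,snps_per_chromosome map dimensions.
#' @param maf_law list: \code{lo}, \code{hi} (uniform MAF range),
#'   \code{rare_frac} (fraction of SNPs drawn from a rare tail),
#'   \code{rare_lo} (lower MAF bound of the tail).
#' @param ld_decay adjacent-marker copying probability in [0, 1]; 0 gives
#'   independent markers.
#' @param recomb_rate per-interval recombination probability for
#'   gene-dropping; default \code{1/snps_per_chromosome} (about one
#'   crossover per chromosome).
#' @param qtl_spec list of regional QTLs, each a list with
#'   \code{chromosome}, \code{window} (SNP indices within that chromosome),
#'   \code{h2_region}, \code{n_causal}, \code{causal_maf_class}
#'   (\code{"common"} or \code{"rare"}).
#' @param h2_poly polygenic variance fraction.
#' @param covariate_effects named vector \code{c(sex=, age=, age2=)}, or a
#'   matrix with one such row per cohort.
#' @param age_range uniform age range in years.
#' @param missing_rate per-call missingness probability.
#' @param n_hwe_violators SNPs overwritten with heterozygote-free genotype
#'   draws (violating HWE strongly), emulating assay failures.
#' @param drop_causal_snps remove the causal SNPs from the emitted genotype
#'   matrix while keeping their phenotypic effect (the ungenotyped-causal
#'   -variant scenario).
#' @param seed integer random seed (< 2^31).
#' @return Validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 2246,
                       n_cohorts = 3,
                       n_families = 300,
                       sibship_size = 3,
                       n_chromosomes = 22,
                       snps_per_chromosome = 500,
                       maf_law = list(lo = 0.01, hi = 0.5,
                                      rare_frac = 0.05, rare_lo = 0.001),
                       ld_decay = 0.9,
                       recomb_rate = NULL,
                       qtl_spec = list(list(chromosome = 16,
                                            window = 401:500,
                                            h2_region = 0.04,
                                            n_causal = 5,
                                            causal_maf_class = "common")),
                       h2_poly = 0.45,
                       covariate_effects = c(sex = 0.5, age = 0.02,
                                             age2 = -2e-4),
                       age_range = c(18, 90),
                       missing_rate = 0.005,
                       n_hwe_violators = 10,
                       drop_causal_snps = FALSE,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$recomb_rate)) cfg$recomb_rate <- 1 / snps_per_chromosome
  counts <- c(n_samples, n_cohorts, n_chromosomes, snps_per_chromosome)
  if (any(counts < 1)) stop("counts must be positive")
  if (n_families < 0 || sibship_size < 0 || n_hwe_violators < 0)
    stop("counts must be non-negative")
  if (n_families * (2 + sibship_size) > n_samples)
    stop("families need ", n_families * (2 + sibship_size),
         " samples but n_samples = ", n_samples)
  fr <- c(h2_poly, ld_decay, missing_rate, cfg$recomb_rate,
          vapply(qtl_spec, function(q) q$h2_region, numeric(1)))
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  h2_tot <- h2_poly + sum(vapply(qtl_spec, function(q) q$h2_region,
                                 numeric(1)))
  if (h2_tot >= 1)
    stop("h2_poly + sum(h2_region) must be < 1 (got ", h2_tot, ")")
  for (q in qtl_spec) {
    if (q$chromosome < 1 || q$chromosome > n_chromosomes)
      stop("QTL chromosome ", q$chromosome, " outside the simulated map")
    if (any(q$window < 1 | q$window > snps_per_chromosome))
      stop("QTL window indices outside 1..", snps_per_chromosome)
    if (q$n_causal < 1 || q$n_causal > length(q$window))
      stop("n_causal must lie in 1..window size")
    if (!q$causal_maf_class %in% c("common", "rare"))
      stop("causal_maf_class must be 'common' or 'rare'")
  }
  if (!is.matrix(covariate_effects)) {
    covariate_effects <- matrix(covariate_effects, n_cohorts, 3,
                                byrow = TRUE,
                                dimnames = list(NULL,
                                                c("sex", "age", "age2")))
  } else if (nrow(covariate_effects) != n_cohorts)
    stop("covariate_effects matrix needs one row per cohort")
  cfg$covariate_effects <- covariate_effects
  if (abs(seed) >= 2^31) stop("seed must be below 2^31")
  structure(cfg, class = "sim_config")
}

# draw per-SNP allele-B frequencies from the configured MAF law
draw_mafs <- function(m, law) {
  p <- stats::runif(m, law$lo, law$hi)
  if (law$rare_frac > 0) {
    rare <- stats::runif(m) < law$rare_frac
    p[rare] <- stats::runif(sum(rare), law$rare_lo, law$lo)
  }
  p
}

# haplotypes with first-order copying LD: a latent uniform is shared with
# the previous marker with probability ld, so allele_k = (u_k < p_k) keeps
# its marginal Bernoulli(p_k) while adjacent markers correlate
draw_haplotypes <- function(n_hap, p, ld) {
  m <- length(p)
  u <- matrix(stats::runif(n_hap * m), n_hap, m)
  if (ld > 0 && m > 1) {
    refresh <- matrix(stats::runif(n_hap * m) >= ld, n_hap, m)
    for (k in 2:m) {
      stay <- !refresh[, k]
      u[stay, k] <- u[stay, k - 1]
    }
  }
  sweep(u, 2, p, "<") * 1
}

# one gamete per row: Mendelian transmission with recombination between
# adjacent SNPs, vectorized over gametes via a running xor of switches
drop_gametes <- function(hap1, hap2, recomb_rate) {
  n <- nrow(hap1)
  m <- ncol(hap1)
  state <- matrix(FALSE, n, m)
  state[, 1] <- stats::runif(n) < 0.5
  if (m > 1) {
    sw <- matrix(stats::runif(n * (m - 1)) < recomb_rate, n, m - 1)
    for (k in 2:m) state[, k] <- xor(state[, k - 1], sw[, k - 1])
  }
  ifelse(state, hap2, hap1)
}

#' Simulate related genotype cohorts
#'
#' Founder haplotypes are drawn per SNP from the configured MAF law with
#' first-order copying LD; family members arise by gene-dropping (Mendelian
#' transmission with recombination between adjacent SNPs). Dosages are coded
#' 0 / 0.5 / 1 for AA / AB / BB. \code{n_hwe_violators} SNPs are then
#' overwritten with heterozygote-free draws, and missing calls are inserted
#' uniformly at \code{missing_rate}. Fully reproducible from
#' \code{config$seed}: the generator uses R's default Mersenne-Twister
#' stream seeded once at entry.
#'
#' The complete (pre-missingness) dosages and the sample registry travel as
#' attributes \code{"complete_values"} and \code{"registry"} so that
#' [simulate_phenotypes()] can act on unobserved causal genotypes.
#'
#' @param config a [sim_config()].
#' @return A \code{genotype_matrix} with attributes \code{complete_values}
#'   (dosages before missingness), \code{registry} (data.frame sample_id,
#'   cohort, sex = NA placeholder, family_id, role) and
#'   \code{hwe_violators} (snp ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  n_fam <- config$n_families
  sib <- config$sibship_size
  n_in_fam <- n_fam * (2 + sib)
  n_single <- n - n_in_fam
  n_founder <- 2 * n_fam + n_single

  # registry: parents then sibs per family, then singletons; families and
  # singletons dealt round-robin across cohorts
  fam_id <- c(rep(seq_len(n_fam), each = 2 + sib),
              rep(NA_integer_, n_single))
  role <- c(rep(c("founder", "founder", rep("offspring", sib)), n_fam),
            rep("founder", n_single))
  cohort_of_fam <- if (n_fam) ((seq_len(n_fam) - 1) %% config$n_cohorts) + 1
  cohort <- c(rep(cohort_of_fam, each = 2 + sib),
              if (n_single)
                ((seq_len(n_single) - 1) %% config$n_cohorts) + 1)
  registry <- data.frame(
    sample_id = sprintf("ind%04d", seq_len(n)),
    cohort = paste0("cohort", cohort),
    family_id = fam_id, role = role, stringsAsFactors = FALSE)

  # founder index of each sample's two haplotypes
  founder_of <- integer(n)  # 0 for offspring
  fi <- 0L
  for (i in seq_len(n)) {
    if (role[i] == "founder") {
      fi <- fi + 1L
      founder_of[i] <- fi
    }
  }

  m_c <- config$snps_per_chromosome
  values <- matrix(NA_real_, n, config$n_chromosomes * m_c)
  mafs <- numeric(config$n_chromosomes * m_c)
  for (chr in seq_len(config$n_chromosomes)) {
    p <- draw_mafs(m_c, config$maf_law)
    H <- draw_haplotypes(2 * n_founder, p, config$ld_decay)
    h1 <- matrix(0, n, m_c)
    h2 <- matrix(0, n, m_c)
    isf <- founder_of > 0
    h1[isf, ] <- H[2 * founder_of[isf] - 1, , drop = FALSE]
    h2[isf, ] <- H[2 * founder_of[isf], , drop = FALSE]
    if (n_fam) {
      off <- which(role == "offspring")
      # parents are the first two members of each family block
      fam_first <- match(fam_id[off], fam_id)
      h1[off, ] <- drop_gametes(h1[fam_first, , drop = FALSE],
                                h2[fam_first, , drop = FALSE],
                                config$recomb_rate)
      h2[off, ] <- drop_gametes(h1[fam_first + 1L, , drop = FALSE],
                                h2[fam_first + 1L, , drop = FALSE],
                                config$recomb_rate)
    }
    cols <- (chr - 1) * m_c + seq_len(m_c)
    values[, cols] <- (h1 + h2) / 2
    mafs[cols] <- p
  }

  variants <- data.frame(
    snp_id = sprintf("snp%d_%d", rep(seq_len(config$n_chromosomes),
                                     each = m_c),
                     rep(seq_len(m_c), config$n_chromosomes)),
    chromosome = rep(seq_len(config$n_chromosomes), each = m_c),
    position = rep(seq_len(m_c) * 10000L, config$n_chromosomes),
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)

  # HWE violators: heterozygote-free draws at intermediate frequency,
  # outside any QTL window so trait architecture is untouched
  qtl_cols <- unlist(lapply(config$qtl_spec, function(q)
    (q$chromosome - 1) * m_c + q$window))
  violators <- integer(0)
  if (config$n_hwe_violators > 0) {
    pool <- setdiff(seq_len(ncol(values)), qtl_cols)
    violators <- sort(sample(pool, min(config$n_hwe_violators,
                                       length(pool))))
    for (j in violators) {
      pv <- stats::runif(1, 0.2, 0.5)
      values[, j] <- sample(c(0, 1), n, replace = TRUE,
                            prob = c(1 - pv, pv))
    }
  }

  complete <- values
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(values)) < config$missing_rate,
                   nrow(values), ncol(values))
    values[miss] <- NA_real_
  }

  gm <- genotype_matrix(values, variants, registry$sample_id)
  attr(gm, "complete_values") <- complete
  attr(gm, "registry") <- registry
  attr(gm, "hwe_violators") <- variants$snp_id[violators]
  attr(gm, "seed") <- config$seed
  gm
}

#' Simulate phenotypes on top of simulated genotypes
#'
#' Builds the trait as covariate part (sex, age, age squared with the
#' configured per-cohort coefficients) + regional QTL part (equal-weight sum
#' of standardized causal dosages scaled to \code{h2_region}) + polygenic
#' part (independent normal weights on the standardized non-causal dosages,
#' scaled to \code{h2_poly}) + normal residual scaled so the non-covariate
#' components sum to unit variance. The polygenic part is residualized
#' in-sample against the regional parts (and the residual against both)
#' before scaling, so each component's realized variance fraction equals its
#' target exactly; \code{truth} records the realized fractions.
#'
#' Causal dosages are taken from the complete (pre-missingness) genotypes;
#' with \code{drop_causal_snps} the causal SNPs are removed from the emitted
#' genotype matrix while their effect persists.
#'
#' @param genotypes output of [simulate_genotypes()] (carrying the
#'   \code{complete_values} and \code{registry} attributes).
#' @param samples sample registry; defaults to the registry attribute.
#' @param config the same [sim_config()] used for the genotypes.
#' @return A \code{simulated_cohort}: list with \code{genotypes} (emitted
#'   matrix, causal SNPs dropped if configured), \code{samples} (registry
#'   with sex and age filled in), \code{phenotype} (data.frame sample_id,
#'   cohort, sex, age, trait) and \code{truth} (realized variance fractions,
#'   causal snp ids and positions, covariate coefficients, seed).
#' @export
simulate_phenotypes <- function(genotypes, samples = NULL, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  if (is.null(samples)) samples <- attr(genotypes, "registry")
  if (is.null(samples) || nrow(samples) != length(genotypes$samples))
    stop("sample registry not aligned to genotypes")
  set.seed(config$seed + 1L)
  G <- attr(genotypes, "complete_values")
  if (is.null(G)) {
    G <- genotypes$values
    for (j in seq_len(ncol(G)))
      if (anyNA(G[, j])) G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
  }
  n <- nrow(G)
  m_c <- config$snps_per_chromosome

  cohort_idx <- match(samples$cohort, unique(samples$cohort))
  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  B <- config$covariate_effects
  covar <- B[cohort_idx, "sex"] * sex + B[cohort_idx, "age"] * age +
    B[cohort_idx, "age2"] * age^2

  p_all <- colMeans(G)
  scale_to <- function(x, v) {
    if (v == 0) return(rep(0, length(x)))
    sx <- stats::var(x)
    if (sx == 0) stop("component has zero variance, cannot scale")
    x * sqrt(v / sx)
  }

  causal <- integer(0)
  regional <- vector("list", length(config$qtl_spec))
  for (qi in seq_along(config$qtl_spec)) {
    q <- config$qtl_spec[[qi]]
    cols <- (q$chromosome - 1) * m_c + q$window
    p <- p_all[cols]
    maf <- pmin(p, 1 - p)
    poly_ok <- p > 0 & p < 1
    if (!any(poly_ok))
      stop("QTL window on chromosome ", q$chromosome,
           " (SNPs ", min(q$window), "-", max(q$window),
           ") contains no polymorphic SNP")
    keep <- if (q$causal_maf_class == "common") poly_ok & maf >= 0.05
            else poly_ok & maf < 0.05
    if (!any(keep)) {
      warning("QTL window has no ", q$causal_maf_class,
              " SNP; using any polymorphic SNP")
      keep <- poly_ok
    }
    pick <- sample(which(keep), min(q$n_causal, sum(keep)))
    if (length(pick) < q$n_causal)
      warning("QTL window supplied only ", length(pick), " causal SNPs")
    cc <- cols[pick]
    Z <- sweep(G[, cc, drop = FALSE], 2, p_all[cc], "-")
    Z <- sweep(Z, 2, sqrt(p_all[cc] * (1 - p_all[cc]) / 2), "/")
    regional[[qi]] <- scale_to(rowSums(Z), q$h2_region)
    causal <- c(causal, cc)
  }

  # later components are residualized in-sample against earlier ones before
  # scaling, so the realized variance fractions equal the targets exactly
  # (LD and finite-sample covariance would otherwise perturb the total)
  ortho_to <- function(x, basis) {
    basis <- Filter(function(b) stats::var(b) > 0, basis)
    if (!length(basis)) return(x)
    B <- cbind(1, do.call(cbind, basis))
    cf <- qr.coef(qr(B), x)
    cf[is.na(cf)] <- 0
    x - B %*% cf
  }
  bg <- setdiff(seq_len(ncol(G)), causal)
  bg <- bg[p_all[bg] > 0 & p_all[bg] < 1]
  if (config$h2_poly > 0) {
    u <- stats::rnorm(length(bg))
    s <- sqrt(p_all[bg] * (1 - p_all[bg]) / 2)
    poly <- as.numeric(G[, bg, drop = FALSE] %*% (u / s)) -
      sum(p_all[bg] * u / s)
    poly <- scale_to(as.numeric(ortho_to(poly, regional)), config$h2_poly)
  } else poly <- rep(0, n)

  h2_regions <- vapply(config$qtl_spec, function(q) q$h2_region, numeric(1))
  resid <- scale_to(as.numeric(ortho_to(stats::rnorm(n),
                                        c(regional, list(poly)))),
                    1 - config$h2_poly - sum(h2_regions))

  reg_sum <- if (length(regional)) Reduce(`+`, regional) else rep(0, n)
  gpart <- reg_sum + poly + resid
  y <- covar + gpart
  vg <- stats::var(gpart)

  samples$sex <- sex
  samples$age <- age
  phenotype <- data.frame(sample_id = samples$sample_id,
                          cohort = samples$cohort, sex = sex, age = age,
                          trait = y, stringsAsFactors = FALSE)
  truth <- list(
    h2_region_nominal = h2_regions,
    h2_region_realized = vapply(regional, function(r) stats::var(r) / vg,
                                numeric(1)),
    h2_poly_nominal = config$h2_poly,
    h2_poly_realized = stats::var(poly) / vg,
    causal_snp_ids = genotypes$variants$snp_id[causal],
    causal_positions = genotypes$variants$position[causal],
    causal_chromosomes = genotypes$variants$chromosome[causal],
    covariate_effects = config$covariate_effects,
    seed = config$seed)

  emitted <- genotypes
  if (config$drop_causal_snps && length(causal)) {
    keep <- setdiff(seq_len(ncol(genotypes$values)), causal)
    emitted <- subset_genotypes(genotypes, snps = keep)
    attr(emitted, "registry") <- samples
  }
  attr(emitted, "complete_values") <- NULL  # emitted data only

  structure(list(genotypes = emitted, samples = samples,
                 phenotype = phenotype, truth = truth),
            class = "simulated_cohort")
}

#' Simulate a full cohort (genotypes + phenotypes)
#'
#' @param config a [sim_config()].
#' @return A \code{simulated_cohort}; see [simulate_phenotypes()].
#' @export
simulate_cohort <- function(config) {
  gm <- simulate_genotypes(config)
  simulate_phenotypes(gm, config = config)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated cohort:", nrow(x$phenotype), "samples,",
      nrow(x$genotypes$variants), "emitted SNPs\n")
  cat(sprintf("  realized h2_poly %.3f; regional: %s\n",
              x$truth$h2_poly_realized,
              paste(sprintf("%.3f", x$truth$h2_region_realized),
                    collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' PLINK .bed/.bim/.fam for the emitted genotypes, a phenotype TSV
#' (sample_id, cohort, sex, age, trait) and a truth JSON.
#'
#' @param cohort a \code{simulated_cohort}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  write_plink(cohort$genotypes, prefix)
  utils::write.table(cohort$phenotype, paste0(prefix, ".pheno.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$covariate_effects <- as.data.frame(truth$covariate_effects)
  jsonlite::write_json(truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
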