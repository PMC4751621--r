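#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table.
#' At stringent thresholds (e.g. 1e-8) the chi-square approximation is
#' unreliable when genotype classes are small, so the exact distribution is
#' enumerated directly.
#'
#' @param n_AA,n_AB,n_BB non-negative genotype counts.
#' @return Exact two-sided p-value; monomorphic SNPs return 1 by convention.
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfect HWE, p = 1
#' hwe_exact_test(50, 0, 50)    # no heterozygotes, p << 1e-8
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_AB + n_BB
  if (n == 0) stop("no genotypes")
  nB <- 2L * n_BB + n_AB
  nA <- 2L * n_AA + n_AB
  if (nA == 0L || nB == 0L) return(1)  # monomorphic
  rare <- min(nA, nB)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(nAB = h | nA, nB) up to a shared constant:
  #   log n! - log nAA! - log nAB! - log nBB! + nAB log 2
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1) + hets * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_AB, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with alleles")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Exact HWE p-values for every SNP of a genotype matrix
#'
#' @param genotypes a \code{genotype_matrix}.
#' @return Numeric vector of exact HWE p-values (monomorphic SNPs get 1).
#' @export
hwe_test_all <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  x <- genotypes$values
  nAA <- colSums(x == 0, na.rm = TRUE)
  nAB <- colSums(x == 0.5, na.rm = TRUE)
  nBB <- colSums(x == 1, na.rm = TRUE)
  vapply(seq_len(ncol(x)),
         function(k) hwe_exact_test(nAA[k], nAB[k], nBB[k]), numeric(1))
}
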