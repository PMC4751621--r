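#' Quality-control thresholds
#'
#' Defaults follow common array-QC practice for family cohorts: discard SNPs
#' with MAF strictly below 0.001 (SNPs at exactly 0.001 are kept), exact HWE
#' p strictly below 1e-8, or call rate below 0.98, then individuals with call
#' rate below 0.98.
#'
#' @param maf_min minimum minor-allele frequency (strict inequality).
#' @param hwe_p_floor minimum exact HWE p-value (strict inequality).
#' @param snp_call_rate_min minimum per-SNP call rate.
#' @param sample_call_rate_min minimum per-individual call rate.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(maf_min = 0.001, hwe_p_floor = 1e-8,
                          snp_call_rate_min = 0.98,
                          sample_call_rate_min = 0.98) {
  th <- list(maf_min = maf_min, hwe_p_floor = hwe_p_floor,
             snp_call_rate_min = snp_call_rate_min,
             sample_call_rate_min = sample_call_rate_min)
  if (any(unlist(th) < 0) || any(unlist(th) > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Apply per-SNP and per-individual quality control
#'
#' Filter order (deterministic, single pass unless \code{iterate}): SNPs by
#' call rate, then MAF, then exact HWE, all computed on the current sample
#' set; then individuals by call rate over the surviving SNPs. With
#' \code{iterate = TRUE} the pass is repeated until no further removal (the
#' sample removals can change per-SNP statistics).
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param thresholds a [qc_thresholds()] object.
#' @param iterate repeat until fixpoint?
#' @return List with \code{genotypes} (filtered) and \code{report}, a
#'   \code{qc_report} recording counts and removed ids per criterion.
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds(),
                     iterate = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n_in <- length(genotypes$samples)
  m_in <- nrow(genotypes$variants)
  removed <- list(snp_call_rate = character(0), maf = character(0),
                  hwe = character(0), sample_call_rate = character(0))
  gm <- genotypes
  repeat {
    changed <- FALSE

    cr <- call_rates(gm)$snp
    drop <- cr < thresholds$snp_call_rate_min
    # all-missing SNPs have no frequency; they fail call rate by definition
    drop <- drop | colSums(!is.na(gm$values)) == 0
    if (any(drop)) {
      removed$snp_call_rate <- c(removed$snp_call_rate,
                                 gm$variants$snp_id[drop])
      gm <- subset_genotypes(gm, snps = which(!drop))
      changed <- TRUE
    }
    if (nrow(gm$variants) == 0) stop("empty after QC: all SNPs removed")

    p <- allele_frequencies(gm)
    maf <- pmin(p, 1 - p)
    drop <- maf < thresholds$maf_min
    if (any(drop)) {
      removed$maf <- c(removed$maf, gm$variants$snp_id[drop])
      gm <- subset_genotypes(gm, snps = which(!drop))
      changed <- TRUE
    }
    if (nrow(gm$variants) == 0) stop("empty after QC: all SNPs removed")

    if (thresholds$hwe_p_floor > 0) {
      hp <- hwe_test_all(gm)
      drop <- hp < thresholds$hwe_p_floor
      if (any(drop)) {
        removed$hwe <- c(removed$hwe, gm$variants$snp_id[drop])
        gm <- subset_genotypes(gm, snps = which(!drop))
        changed <- TRUE
      }
      if (nrow(gm$variants) == 0) stop("empty after QC: all SNPs removed")
    }

    scr <- call_rates(gm)$sample
    drop <- scr < thresholds$sample_call_rate_min
    if (any(drop)) {
      removed$sample_call_rate <- c(removed$sample_call_rate,
                                    gm$samples[drop])
      gm <- subset_genotypes(gm, samples = which(!drop))
      changed <- TRUE
    }
    if (length(gm$samples) == 0) stop("empty after QC: all samples removed")

    if (!iterate || !changed) break
  }
  report <- structure(
    list(n_snps_in = m_in, n_snps_out = nrow(gm$variants),
         n_samples_in = n_in, n_samples_out = length(gm$samples),
         n_removed = vapply(removed, length, integer(1)),
         removed = removed, thresholds = thresholds, iterated = iterate),
    class = "qc_report")
  list(genotypes = gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat(sprintf("  SNPs: %d in, %d out\n", x$n_snps_in, x$n_snps_out))
  cat(sprintf("  samples: %d in, %d out\n", x$n_samples_in, x$n_samples_out))
  for (nm in names(x$n_removed))
    cat(sprintf("  removed by %s: %d\n", nm, x$n_removed[[nm]]))
  invisible(x)
}
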