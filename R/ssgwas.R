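#' Fit the polygenic null model for single-SNP association
#'
#' REML fit of phenotype = intercept + whole-genome additive effect +
#' residual, with the whole-genome kinship as the random-effect covariance.
#' The returned object carries the eigen decomposition of the kinship, so
#' \eqn{\hat V^{-1} x} products cost one rotation — the per-SNP score tests
#' reuse it without refitting.
#'
#' @param y named phenotype vector (adjusted and rank-transformed).
#' @param G_w whole-genome \code{grm} (or symmetric matrix).
#' @return Object of class \code{polygenic_null}: \code{fit} (the
#'   \code{varcomp_fit}), \code{mu} (GLS intercept), \code{residuals},
#'   \code{Vinv_resid}, rotation pieces (\code{U}, \code{w}), \code{h2}
#'   and a \code{degenerate} flag raised when the kinship carries no
#'   structure (e.g. near-identity) and the polygenic variance is not
#'   identifiable.
#' @export
fit_polygenic_null <- function(y, G_w) {
  K <- if (inherits(G_w, "grm")) G_w$values else G_w
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    if (!setequal(names(y), rownames(K)))
      stop("phenotype names do not match kinship sample ids")
    y <- y[rownames(K)]
  }
  fit <- fit_reml(y, list(w = K))
  U <- fit$eigen$vectors
  wv <- fit$sigma2[["w"]] * fit$eigen$values + fit$sigma2[["e"]]
  if (min(wv) <= 0) stop("fitted V is not positive definite")
  mu <- as.numeric(fit$beta)
  resid <- y - mu
  Vinv_resid <- U %*% (crossprod(U, resid) / wv)
  h2 <- fit$sigma2[["w"]] / sum(fit$sigma2)
  if (fit$degenerate)
    warning("kinship matrix is near-degenerate: polygenic variance not ",
            "identifiable; fit flagged")
  structure(list(fit = fit, mu = mu, residuals = resid,
                 Vinv_resid = as.numeric(Vinv_resid), U = U, w = wv,
                 h2 = h2, degenerate = fit$degenerate,
                 sample_ids = names(y)),
            class = "polygenic_null")
}

#' @export
print.polygenic_null <- function(x, ...) {
  cat(sprintf("polygenic null model: n = %d, h2 = %.3f%s\n",
              length(x$residuals), x$h2,
              if (x$degenerate) " (degenerate kinship)" else ""))
  invisible(x)
}

#' Mixed-model score test of one SNP
#'
#' The kinship-aware score statistic
#' \deqn{T = \frac{[\tilde g' \hat V^{-1} (y - \hat\mu)]^2}
#'   {\tilde g' \hat V^{-1} \tilde g},}
#' with \eqn{\tilde g} the mean-centered dosage (missing dosages
#' mean-imputed for the test only), referred to a one-degree chi-square.
#' With \eqn{\hat\sigma^2_w = 0} this reduces exactly to the classical
#' score test of simple linear regression.
#'
#' @param null_fit a [fit_polygenic_null()] object.
#' @param g dosage vector aligned to the null fit's samples.
#' @return One-row data.frame: \code{stat}, \code{neg_log10_p},
#'   \code{direction} (sign of the score), \code{freq}, \code{flag}
#'   (\code{"ok"} or \code{"monomorphic"}; monomorphic SNPs get no
#'   statistic).
#' @export
score_test <- function(null_fit, g) {
  stopifnot(inherits(null_fit, "polygenic_null"))
  if (length(g) != length(null_fit$residuals))
    stop("dosage vector not aligned to the null fit")
  freq <- mean(g, na.rm = TRUE)
  if (is.nan(freq) || length(unique(g[!is.na(g)])) < 2)
    return(data.frame(stat = NA_real_, neg_log10_p = NA_real_,
                      direction = NA_real_, freq = freq,
                      flag = "monomorphic"))
  g[is.na(g)] <- freq
  gt <- g - mean(g)
  Vinv_g <- null_fit$U %*% (crossprod(null_fit$U, gt) / null_fit$w)
  num <- sum(gt * null_fit$Vinv_resid)
  den <- sum(gt * Vinv_g)
  stat <- num^2 / den
  data.frame(stat = stat,
             neg_log10_p = -stats::pchisq(stat, df = 1, lower.tail = FALSE,
                                          log.p = TRUE) / log(10),
             direction = sign(num), freq = freq, flag = "ok")
}

#' Kinship-aware single-SNP genome scan
#'
#' Applies the mixed-model score test to every SNP, reusing the polygenic
#' null fit. All rotations are done in one matrix product, so the scan is
#' one BLAS call plus column sums. Results are ordered by (chromosome,
#' position); monomorphic SNPs are flagged and carry no statistic.
#'
#' @param null_fit a [fit_polygenic_null()] object.
#' @param genotypes post-QC \code{genotype_matrix} with samples matching the
#'   null fit.
#' @return data.frame: \code{snp_id}, \code{chromosome}, \code{position},
#'   \code{freq}, \code{stat}, \code{neg_log10_p}, \code{direction},
#'   \code{flag}.
#' @export
scan_snps <- function(null_fit, genotypes) {
  stopifnot(inherits(null_fit, "polygenic_null"),
            inherits(genotypes, "genotype_matrix"))
  if (!is.null(null_fit$sample_ids)) {
    if (!setequal(null_fit$sample_ids, genotypes$samples))
      stop("genotype samples do not match the null fit")
    genotypes <- subset_genotypes(
      genotypes, samples = match(null_fit$sample_ids, genotypes$samples))
  }
  G <- genotypes$values
  freq <- colMeans(G, na.rm = TRUE)
  mono <- !is.finite(freq) | freq == 0 | freq == 1 |
    apply(G, 2, function(col) length(unique(col[!is.na(col)])) < 2)
  # mean-impute missing dosages, then center
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- freq[j]
  Gc <- sweep(G, 2, colMeans(G), "-")
  A <- crossprod(null_fit$U, Gc)            # rotate all SNPs at once
  rt <- crossprod(null_fit$U, null_fit$residuals) / null_fit$w
  num <- as.numeric(crossprod(A, rt))
  den <- colSums(A^2 / null_fit$w)
  stat <- num^2 / den
  stat[mono] <- NA_real_
  res <- data.frame(
    snp_id = genotypes$variants$snp_id,
    chromosome = genotypes$variants$chromosome,
    position = genotypes$variants$position,
    freq = freq, stat = stat,
    neg_log10_p = -stats::pchisq(stat, df = 1, lower.tail = FALSE,
                                 log.p = TRUE) / log(10),
    direction = sign(num),
    flag = ifelse(mono, "monomorphic", "ok"))
  res$direction[mono] <- NA_real_
  res$neg_log10_p[mono] <- NA_real_
  res[order(res$chromosome, res$position), ]
}
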