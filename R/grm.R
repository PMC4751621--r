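#' Marker-based genomic relationship matrix
#'
#' Builds the n x n relationship matrix used as the covariance structure of
#' a random genetic effect, from all SNPs (whole-genome role) or from the
#' SNPs of one window (regional role). Off-diagonals are frequency-weighted
#' products of centered dosages,
#' \deqn{f_{ij} = \frac{2}{m_{ij}} \sum_k
#'   \frac{(g_{ik}-p_k)(g_{jk}-p_k)}{p_k(1-p_k)},}
#' summed over SNPs non-missing in both individuals (\eqn{m_{ij}} of them),
#' with dosages \eqn{g \in \{0, 0.5, 1\}} and \eqn{p_k} the allele-B
#' frequency estimated from the analysis sample. Diagonals use the
#' homozygosity-corrected form
#' \deqn{f_{ii} = 1 + \frac{Obs(\#hom)_i - E(\#hom)_i}{m_i - E(\#hom)_i},}
#' where \eqn{E(\#hom)_i = \sum_k (1 - 2 p_k (1-p_k))} over the SNPs
#' non-missing in individual i, so the self-relationship reads 1 plus an
#' estimated inbreeding coefficient. On this scale variance components of a
#' random effect with covariance \eqn{\sigma^2 f} are additive genetic
#' variances.
#'
#' Monomorphic SNPs carry no relationship information and are skipped with a
#' warning.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param snp_subset column indices (or snp_ids) of the SNPs to use; NULL
#'   for all.
#' @param role \code{"whole_genome"} or \code{"regional"}.
#' @return An object of class \code{grm}: list with \code{values} (n x n
#'   symmetric), \code{role}, \code{m} (SNPs used), \code{snp_ids},
#'   \code{allele_freqs}, \code{m_pairs} (pairwise non-missing SNP counts)
#'   and \code{sample_ids}.
#' @export
genomic_relationship <- function(genotypes, snp_subset = NULL,
                                 role = c("whole_genome", "regional")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  role <- match.arg(role)
  if (is.null(snp_subset)) snp_subset <- seq_len(nrow(genotypes$variants))
  if (is.character(snp_subset))
    snp_subset <- match(snp_subset, genotypes$variants$snp_id)
  if (length(snp_subset) == 0) stop("snp_subset is empty")

  G <- genotypes$values[, snp_subset, drop = FALSE]
  p <- colMeans(G, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("SNP subset is entirely monomorphic")
  if (any(!poly))
    warning(sum(!poly), " monomorphic SNP(s) skipped in relationship matrix")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(G)
  n <- nrow(G)

  het <- p * (1 - p)
  S <- sweep(G, 2, p, "-")
  S <- sweep(S, 2, sqrt(het), "/")
  obs <- !is.na(G)
  S[!obs] <- 0
  num <- tcrossprod(S)          # sum_k (g_ik-p)(g_jk-p)/(p(1-p)) over shared SNPs
  m_pairs <- tcrossprod(obs * 1)
  f <- 2 * num / pmax(m_pairs, 1)
  f[m_pairs == 0] <- NA_real_

  # homozygosity-corrected diagonal
  m_i <- diag(m_pairs)
  obs_hom <- rowSums((G == 0 | G == 1) & obs, na.rm = TRUE)
  e_hom <- as.vector(obs %*% (1 - 2 * het))
  denom <- m_i - e_hom
  degen <- abs(denom) < 1e-8
  di <- 1 + (obs_hom - e_hom) / ifelse(degen, 1, denom)
  if (any(degen)) {
    warning(sum(degen), " individual(s) with m_i ~ E(#hom): diagonal falls ",
            "back to the off-diagonal formula with i = j")
    di[degen] <- diag(f)[degen]
  }
  diag(f) <- di
  f <- (f + t(f)) / 2
  dimnames(f) <- list(genotypes$samples, genotypes$samples)

  structure(list(values = f, role = role, m = m,
                 snp_ids = colnames(G), allele_freqs = p,
                 m_pairs = m_pairs, sample_ids = genotypes$samples),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("grm (%s): %d samples, %d SNPs\n", x$role, n, x$m))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x$values)), mean(off)))
  invisible(x)
}

#' Bend a relationship matrix to positive semi-definiteness
#'
#' REML needs usable covariance structures; sampling noise in marker-based
#' matrices can push small eigenvalues slightly negative. If the matrix is
#' already PSD it is returned untouched; otherwise eigenvalues below
#' \code{floor} are raised to \code{floor} and the matrix reconstructed.
#'
#' @param matrix a \code{grm} or a plain symmetric matrix.
#' @param floor small positive eigenvalue floor.
#' @return Same type as the input, PSD up to numerical tolerance.
#' @export
bend_psd <- function(matrix, floor = 1e-6) {
  is_grm <- inherits(matrix, "grm")
  A <- if (is_grm) matrix$values else matrix
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) >= 0) return(matrix)
  lam <- pmax(e$values, floor)
  B <- e$vectors %*% (lam * t(e$vectors))
  B <- (B + t(B)) / 2
  dimnames(B) <- dimnames(A)
  if (is_grm) {
    matrix$values <- B
    matrix
  } else B
}

#' Write a relationship matrix in GCTA text format
#'
#' Emits \code{<prefix>.grm.gz} (gzipped text: lower-triangle rows
#' \code{i j m_ij f_ij}, 1-based, i >= j) and \code{<prefix>.grm.id}
#' (family and individual id columns).
#'
#' @param grm a \code{grm} object.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  ij <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(
    data.frame(ij[, 1], ij[, 2],
               grm$m_pairs[ij], signif(grm$values[ij], 10)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA-format relationship matrix
#'
#' @param prefix path prefix of a \code{.grm.gz}/\code{.grm.id} pair.
#' @param role role label for the returned \code{grm}.
#' @return A \code{grm} object (allele frequencies and snp ids are not part
#'   of the GCTA format and are NA).
#' @export
read_grm <- function(prefix, role = "whole_genome") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  n <- length(ids)
  tab <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  idx <- cbind(tab[[1]], tab[[2]])
  A[idx] <- tab[[4]]
  M[idx] <- tab[[3]]
  A[idx[, 2:1, drop = FALSE]] <- tab[[4]]
  M[idx[, 2:1, drop = FALSE]] <- tab[[3]]
  structure(list(values = A, role = role, m = max(M), snp_ids = NULL,
                 allele_freqs = NULL, m_pairs = M, sample_ids = ids),
            class = "grm")
}
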