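#' Regional heritability scan over SNP windows
#'
#' For each window, builds the regional relationship matrix from the
#' window's SNPs, fits the full model (whole-genome + regional random
#' effects + residual) by REML, and compares it with the shared null model
#' (whole-genome effect only, fitted once per scan — it does not depend on
#' the window) by a boundary likelihood-ratio test. The whole-genome matrix
#' retains the window's SNPs; no leave-region-out is applied. Reports per
#' window the LRT, -log10 p (see [lrt_to_neg_log10_p()]), the regional
#' heritability \eqn{h^2_r = \sigma^2_r/\sigma^2_p} and the whole-genome
#' heritability \eqn{h^2_w = \sigma^2_w/\sigma^2_p}, with
#' \eqn{\sigma^2_p = \sigma^2_w + \sigma^2_r + \sigma^2_e}.
#'
#' Window fits start from the null solution (with a small regional
#' variance), and the null parameters are always retained as a candidate, so
#' the full-model likelihood can never fall below the null: a window with no
#' regional signal reports LRT = 0. Per-window failures are flagged and
#' excluded from the summary; they never abort the scan.
#'
#' @param y named numeric phenotype vector (adjusted and rank-transformed),
#'   names matching the genotype sample ids.
#' @param genotypes post-QC \code{genotype_matrix}.
#' @param windows a \code{window_spec} from [make_windows()].
#' @param G_w whole-genome \code{grm} (bend with [bend_psd()] first).
#' @param null_fit optional pre-computed null \code{varcomp_fit} (reused
#'   across the genome scan and fine mapping).
#' @param lrt_method null law for the LRT, see [lrt_to_neg_log10_p()].
#' @param verbose print progress every 50 windows?
#' @return List of class \code{region_scan}: \code{results} (one row per
#'   window: window columns, \code{LRT}, \code{neg_log10_p},
#'   \code{h2_region}, \code{h2_whole}, variance components,
#'   \code{converged}), \code{null_fit} and \code{summary} (mean and
#'   standard error of \code{h2_whole} across converged windows).
#' @export
scan_regions <- function(y, genotypes, windows, G_w, null_fit = NULL,
                         lrt_method = c("chisq_half", "mixture"),
                         verbose = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(G_w, "grm"))
  lrt_method <- match.arg(lrt_method)
  if (!is.null(names(y))) {
    if (!setequal(names(y), genotypes$samples))
      stop("phenotype names do not match genotype sample ids")
    y <- y[genotypes$samples]
  } else if (length(y) != length(genotypes$samples))
    stop("unnamed phenotype of wrong length")

  if (is.null(null_fit))
    null_fit <- fit_reml(y, list(w = G_w))
  # re-evaluate the null restricted likelihood through the dense evaluator
  # so LRT differences compare likelihoods computed by the same route
  s2w0 <- null_fit$sigma2[["w"]]
  s2e0 <- null_fit$sigma2[["e"]]
  null_ll <- reml_loglik(y, list(G_w), c(s2w0, s2e0))
  vy <- stats::var(y)
  n <- length(y)

  # boundary screen: the REML score for sigma2_r at the null solution,
  # d l / d sigma2_r = (y'P G_r P y - tr(P G_r)) / 2, costs O(n^2) per
  # window once V^-1 under the null is cached. A non-positive score (plus
  # two probe evaluations as insurance against non-monotone profiles) means
  # the boundary sigma2_r = 0 is the REML solution and the window's LRT is
  # exactly 0, so the optimizer run is skipped.
  if (!is.null(null_fit$eigen)) {
    wv <- s2w0 * null_fit$eigen$values + s2e0
    Vinv <- null_fit$eigen$vectors %*%
      (t(null_fit$eigen$vectors) / wv)
  } else {
    Vinv <- solve(s2w0 * G_w$values + diag(s2e0, length(y)))
  }
  ones <- rep(1, n)
  Vinv1 <- Vinv %*% ones
  s11 <- sum(Vinv1)
  Py <- as.numeric(Vinv %*% y - Vinv1 * (sum(Vinv1 * y) / s11))

  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    rows[[i]] <- tryCatch({
      G_r <- suppressWarnings(
        genomic_relationship(genotypes, window_snps(w), role = "regional"))
      Gr <- G_r$values
      tr_PG <- sum(Vinv * Gr) -
        as.numeric(crossprod(Vinv1, Gr %*% Vinv1)) / s11
      score_r <- 0.5 * (as.numeric(crossprod(Py, Gr %*% Py)) - tr_PG)
      at_boundary <- FALSE
      if (score_r <= 1e-8) {
        probes <- vapply(c(0.02, 0.1) * vy, function(s2r)
          reml_loglik(y, list(G_w, G_r), c(s2w0, s2r, s2e0)), numeric(1))
        at_boundary <- all(probes <= null_ll + 1e-6)
      }
      if (at_boundary) {
        s2 <- c(w = s2w0, r = 0, e = s2e0)
        stat <- 0
        conv <- TRUE
      } else {
        full <- fit_reml(y, list(w = G_w, r = G_r),
                         start = c(max(s2w0, 0.05 * vy), 0.02 * vy,
                                   max(s2e0, 0.05 * vy)))
        stat <- max(0, 2 * (max(full$loglik, null_ll) - null_ll))
        s2 <- full$sigma2
        conv <- full$converged
      }
      s2p <- sum(s2)
      data.frame(w, LRT = stat,
                 neg_log10_p = lrt_to_neg_log10_p(stat, lrt_method),
                 h2_region = s2[["r"]] / s2p, h2_whole = s2[["w"]] / s2p,
                 sigma2_w = s2[["w"]], sigma2_r = s2[["r"]],
                 sigma2_e = s2[["e"]], converged = conv)
    }, error = function(e) {
      warning("window ", w$window_id, " failed: ", conditionMessage(e))
      data.frame(w, LRT = NA_real_, neg_log10_p = NA_real_,
                 h2_region = NA_real_, h2_whole = NA_real_,
                 sigma2_w = NA_real_, sigma2_r = NA_real_,
                 sigma2_e = NA_real_, converged = FALSE)
    })
    if (verbose && i %% 50 == 0)
      message("  window ", i, "/", nrow(windows))
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- results$converged & !is.na(results$h2_whole)
  summary <- list(
    n_windows = nrow(results), n_converged = sum(ok),
    h2_whole_mean = mean(results$h2_whole[ok]),
    h2_whole_se = stats::sd(results$h2_whole[ok]) / sqrt(max(sum(ok), 1)),
    lrt_method = lrt_method)
  structure(list(results = results, null_fit = null_fit, summary = summary),
            class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("regional heritability scan: %d windows (%d converged)\n",
              s$n_windows, s$n_converged))
  cat(sprintf("  whole-genome h2: %.3f (s.e. %.3f), averaged across windows\n",
              s$h2_whole_mean, s$h2_whole_se))
  top <- x$results[order(-x$results$LRT), ][1, ]
  cat(sprintf("  top window %d (chr %d, %d-%d bp): LRT %.2f, -log10 p %.2f, h2_region %.3f\n",
              top$window_id, top$chromosome, top$bp_start, top$bp_end,
              top$LRT, top$neg_log10_p, top$h2_region))
  invisible(x)
}

#' Fine-map the top windows of a genome scan
#'
#' Re-scans the \code{k} highest-LRT windows with small windows (default
#' 10-SNP size, 5-SNP overlap), reusing the genome scan's null fit.
#'
#' @param scan a \code{region_scan} from the 100-SNP genome scan.
#' @param genotypes,G_w as in [scan_regions()].
#' @param y phenotype used for the genome scan.
#' @param k number of top windows to follow up (default 100).
#' @param size,stride fine-window geometry.
#' @param ... passed to [scan_regions()].
#' @return A \code{region_scan} over the fine windows (the window table
#'   carries \code{parent_window_id}).
#' @export
fine_map_scan <- function(scan, y, genotypes, G_w, k = 100, size = 10,
                          stride = 5, ...) {
  stopifnot(inherits(scan, "region_scan"))
  sel <- select_fine_map_targets(scan$results, genotypes$variants, k = k,
                                 size = size, stride = stride)
  scan_regions(y, genotypes, sel$windows, G_w, null_fit = scan$null_fit, ...)
}
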