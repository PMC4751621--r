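#' Bonferroni genome-wide significance threshold
#'
#' \code{-log10(alpha / m)} with \code{m = n_tests / 2} when \code{halve} is
#' set. Overlapping-window scans halve the raw window count to approximate
#' the number of independent tests (each SNP appears in two windows at 50%
#' overlap); the halved count may be fractional and is used as-is.
#'
#' @param n_tests number of tests performed (SNPs or windows).
#' @param alpha family-wise error rate (default 0.05).
#' @param halve halve the test count for overlapping windows?
#' @return Threshold on the -log10 p scale (full precision; round to 2
#'   decimals for display).
#' @examples
#' bonferroni_threshold(268651)              # 6.73, single-SNP scan
#' bonferroni_threshold(5373, halve = TRUE)  # 4.73, 100-SNP windows
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05, halve = FALSE) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- if (halve) n_tests / 2 else n_tests
  -log10(alpha / m)
}

#' Suggestive significance threshold
#'
#' The level at which one false positive per genome scan is expected:
#' \code{-log10(1 / m)} with the same (optionally halved) effective test
#' count as [bonferroni_threshold()].
#'
#' @inheritParams bonferroni_threshold
#' @return Threshold on the -log10 p scale.
#' @examples
#' suggestive_threshold(268651)               # 5.43
#' suggestive_threshold(53732, halve = TRUE)  # 4.43
#' @export
suggestive_threshold <- function(n_tests, halve = FALSE) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  m <- if (halve) n_tests / 2 else n_tests
  log10(m)
}

#' Threshold set for one analysis class
#'
#' Bundles the genome-wide and suggestive thresholds for a scan class:
#' single-SNP scans use the raw test count, overlapping-window scans
#' (100-SNP and 10-SNP) halve it.
#'
#' @param class \code{"ssgwas"}, \code{"window100"} or \code{"window10"}.
#' @param n_tests_raw number of tests actually performed in this scan.
#' @param alpha family-wise error rate.
#' @return List of class \code{threshold_set} with the raw and effective
#'   test counts and both thresholds.
#' @export
threshold_set <- function(class = c("ssgwas", "window100", "window10"),
                          n_tests_raw, alpha = 0.05) {
  class <- match.arg(class)
  halve <- class != "ssgwas"
  out <- list(class = class, n_tests_raw = n_tests_raw,
              n_tests_effective = if (halve) n_tests_raw / 2 else n_tests_raw,
              alpha = alpha,
              genomewide = bonferroni_threshold(n_tests_raw, alpha, halve),
              suggestive = suggestive_threshold(n_tests_raw, halve))
  structure(out, class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "%s thresholds (alpha = %g, %g tests, %g effective):\n  genome-wide %.2f, suggestive %.2f (-log10 p)\n",
    x$class, x$alpha, x$n_tests_raw, x$n_tests_effective,
    x$genomewide, x$suggestive))
  invisible(x)
}
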