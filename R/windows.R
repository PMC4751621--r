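#' Define sliding SNP windows along the genome
#'
#' The regional units of the scan: runs of \code{size} consecutive genotyped
#' SNPs advanced by \code{stride} SNPs (overlap = size - stride), never
#' crossing a chromosome boundary. Within each chromosome starts are 0,
#' stride, 2*stride, ...; when the next window would run past the last SNP a
#' final window is anchored at the chromosome end so every SNP is covered at
#' full window size where possible (\code{terminal = "anchor"}), or the last
#' partial window is truncated (\code{terminal = "truncate"}). A chromosome
#' with fewer SNPs than \code{size} yields a single whole-chromosome window
#' with a warning.
#'
#' @param variants data.frame of variant records sorted by (chromosome,
#'   position) — e.g. the \code{variants} element of a
#'   \code{genotype_matrix}.
#' @param size window size in SNPs (100 for the genome scan, 10 for fine
#'   mapping).
#' @param stride advance in SNPs (50 and 5 respectively, giving 50%%
#'   overlap).
#' @param terminal end-of-chromosome rule, \code{"anchor"} (default) or
#'   \code{"truncate"}.
#' @return data.frame of class \code{window_spec}: \code{window_id},
#'   \code{chromosome}, \code{start}, \code{end} (0-based half-open indices
#'   into the chromosome-sorted variant list, global numbering),
#'   \code{bp_start}, \code{bp_end}, \code{size}, \code{first_snp},
#'   \code{last_snp}.
#' @export
make_windows <- function(variants, size, stride,
                         terminal = c("anchor", "truncate")) {
  terminal <- match.arg(terminal)
  if (!(size > stride && stride > 0)) stop("need size > stride > 0")
  ord <- order(variants$chromosome, variants$position)
  if (any(ord != seq_along(ord)))
    stop("variants must be sorted by (chromosome, position)")
  out <- list()
  offset <- 0L
  for (chr in unique(variants$chromosome)) {
    n_c <- sum(variants$chromosome == chr)
    if (n_c < size) {
      warning("chromosome ", chr, " has ", n_c, " SNPs < window size ", size,
              "; single whole-chromosome window")
      starts <- 0L
      ends <- n_c
    } else {
      starts <- integer(0)
      s <- 0L
      repeat {
        if (s + size > n_c) {
          if (terminal == "anchor") starts <- c(starts, max(0L, n_c - size))
          else if (s < n_c) starts <- c(starts, s)
          break
        }
        starts <- c(starts, s)
        s <- s + stride
      }
      starts <- unique(starts)
      ends <- pmin(starts + size, n_c)
    }
    out[[length(out) + 1L]] <- data.frame(
      chromosome = chr, start = offset + starts, end = offset + ends)
    offset <- offset + n_c
  }
  w <- do.call(rbind, out)
  w$window_id <- seq_len(nrow(w))
  w$bp_start <- variants$position[w$start + 1L]
  w$bp_end <- variants$position[w$end]
  w$size <- w$end - w$start
  w$first_snp <- variants$snp_id[w$start + 1L]
  w$last_snp <- variants$snp_id[w$end]
  w <- w[, c("window_id", "chromosome", "start", "end", "bp_start", "bp_end",
             "size", "first_snp", "last_snp")]
  class(w) <- c("window_spec", "data.frame")
  w
}

#' SNP column indices of one window
#'
#' @param window one row of a [make_windows()] result.
#' @return Integer vector of variant-registry column indices.
#' @export
window_snps <- function(window) {
  seq.int(window$start + 1L, window$end)
}

#' Select the top scan windows and lay out fine-mapping windows
#'
#' Ranks genome-scan results by LRT (descending; ties broken by smaller
#' -log10 p, then window_id) and, for each of the top \code{k} windows,
#' generates fine-scale windows (default 10-SNP size, 5-SNP overlap) across
#' its SNP span with [make_windows()].
#'
#' @param results region-scan result data.frame with columns \code{window_id},
#'   \code{LRT}, \code{neg_log10_p} plus the window columns of
#'   [make_windows()] (as returned by [scan_regions()]).
#' @param variants the variant registry the scan windows index into.
#' @param k number of top windows to fine map (default 100).
#' @param size,stride fine-window geometry (defaults 10 and 5).
#' @return List with \code{targets} (the selected top-k result rows in rank
#'   order) and \code{windows} (fine \code{window_spec}, with a
#'   \code{parent_window_id} column).
#' @export
select_fine_map_targets <- function(results, variants, k = 100,
                                    size = 10, stride = 5) {
  if (nrow(results) < 1) stop("no scan results to select from")
  if (k > nrow(results)) {
    warning("k = ", k, " exceeds ", nrow(results),
            " scanned windows; selecting all")
    k <- nrow(results)
  }
  ord <- order(-results$LRT, results$neg_log10_p, results$window_id)
  top <- results[ord[seq_len(k)], , drop = FALSE]
  fine <- lapply(seq_len(nrow(top)), function(i) {
    span <- seq.int(top$start[i] + 1L, top$end[i])
    w <- make_windows(variants[span, , drop = FALSE], size, stride)
    w$start <- w$start + top$start[i]
    w$end <- w$end + top$start[i]
    w$parent_window_id <- top$window_id[i]
    w
  })
  fine <- do.call(rbind, fine)
  fine$window_id <- seq_len(nrow(fine))
  list(targets = top, windows = fine)
}
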