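#' Run the full regional-heritability analysis
#'
#' End-to-end orchestration: genotype QC, per-cohort phenotype adjustment
#' and rank transformation, whole-genome relationship matrix, 100-SNP
#' regional scan, fine mapping of the top windows with 10-SNP windows,
#' single-SNP mixed-model scan, and significance thresholds derived from
#' the counts of tests actually performed (overridable with published
#' counts). Every stage's output is written under \code{out_dir} so stages
#' are independently re-runnable; given identical inputs the result tables
#' are byte-identical (all fits are deterministic).
#'
#' @param genotypes a \code{genotype_matrix} (pre-QC) or a PLINK prefix.
#' @param pheno data.frame with \code{sample_id}, \code{cohort}, \code{sex},
#'   \code{age} and the trait column, or a TSV path.
#' @param trait trait column name.
#' @param out_dir output directory (created if absent); NULL skips writing.
#' @param qc [qc_thresholds()] to apply.
#' @param size,stride genome-scan window geometry (100 / 50).
#' @param fine_size,fine_stride fine-mapping geometry (10 / 5).
#' @param top_k number of top windows to fine map.
#' @param alpha family-wise error rate for thresholds.
#' @param lrt_method LRT null law, see [lrt_to_neg_log10_p()].
#' @param paper_counts optional named list overriding the test counts used
#'   for thresholds (\code{ssgwas}, \code{window100}, \code{window10}).
#' @param verbose log stage progress to stderr?
#' @return List of class \code{rhm_analysis}: \code{qc_report},
#'   \code{phenotype}, \code{scan100}, \code{fine}, \code{ssgwas},
#'   \code{thresholds}, \code{hits} (windows/SNPs at or above each
#'   threshold), \code{files} (paths written).
#' @export
run_full_analysis <- function(genotypes, pheno, trait = "trait",
                              out_dir = NULL, qc = qc_thresholds(),
                              size = 100, stride = 50, fine_size = 10,
                              fine_stride = 5, top_k = 100, alpha = 0.05,
                              lrt_method = c("chisq_half", "mixture"),
                              paper_counts = NULL, verbose = FALSE) {
  lrt_method <- match.arg(lrt_method)
  say <- function(...) if (verbose) message("[rhmscan] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[length(files) + 1]] <<- path
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (is.character(genotypes)) genotypes <- stage("read", read_plink(genotypes))
  if (is.character(pheno))
    pheno <- utils::read.table(pheno, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)

  say("QC on ", length(genotypes$samples), " samples x ",
      nrow(genotypes$variants), " SNPs")
  qcres <- stage("qc", apply_qc(genotypes, qc))
  gm <- qcres$genotypes

  say("phenotype preparation")
  prep <- stage("phenotype", {
    common <- intersect(gm$samples, pheno$sample_id)
    if (length(common) < 30) stop("fewer than 30 samples with phenotype")
    prepare_phenotype(pheno[pheno$sample_id %in% common, ], trait = trait)
  })
  y <- prep$values
  gm <- stage("align", subset_genotypes(
    gm, samples = match(names(y), gm$samples)))
  emit(data.frame(sample_id = names(y), y = y), "phenotype.tsv")

  say("whole-genome relationship matrix (", nrow(gm$variants), " SNPs)")
  G_w <- stage("grm", bend_psd(genomic_relationship(gm, role = "whole_genome")))

  say("100-SNP regional scan")
  windows <- stage("windows", make_windows(gm$variants, size, stride))
  scan100 <- stage("scan100",
                   scan_regions(y, gm, windows, G_w,
                                lrt_method = lrt_method, verbose = verbose))
  emit(format_scan_results(scan100), "rhm_scan100.tsv")

  say("fine mapping top ", top_k, " windows")
  fine <- stage("finemap",
                fine_map_scan(scan100, y, gm, G_w, k = top_k,
                              size = fine_size, stride = fine_stride,
                              lrt_method = lrt_method))
  emit(format_scan_results(fine), "rhm_fine10.tsv")

  say("single-SNP mixed-model scan")
  ssg <- stage("ssgwas", {
    nullfit <- fit_polygenic_null(y, G_w)
    scan_snps(nullfit, gm)
  })
  emit(ssg, "ssgwas.tsv")

  say("thresholds")
  counts <- list(ssgwas = sum(ssg$flag == "ok"),
                 window100 = nrow(scan100$results),
                 window10 = nrow(fine$results))
  if (!is.null(paper_counts)) counts[names(paper_counts)] <- paper_counts
  thr <- list(ssgwas = threshold_set("ssgwas", counts$ssgwas, alpha),
              window100 = threshold_set("window100", counts$window100, alpha),
              window10 = threshold_set("window10", counts$window10, alpha))
  if (!is.null(out_dir)) {
    jsonlite::write_json(lapply(thr, unclass),
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    files[[length(files) + 1]] <- file.path(out_dir, "thresholds.json")
  }

  hits <- list(
    window100_genomewide = subset(scan100$results,
                                  neg_log10_p >= thr$window100$genomewide),
    window100_suggestive = subset(scan100$results,
                                  neg_log10_p >= thr$window100$suggestive),
    window10_genomewide = subset(fine$results,
                                 neg_log10_p >= thr$window10$genomewide),
    ssgwas_genomewide = subset(ssg, !is.na(neg_log10_p) &
                                 neg_log10_p >= thr$ssgwas$genomewide),
    ssgwas_suggestive = subset(ssg, !is.na(neg_log10_p) &
                                 neg_log10_p >= thr$ssgwas$suggestive))

  structure(list(qc_report = qcres$report, phenotype = prep,
                 scan100 = scan100, fine = fine, ssgwas = ssg,
                 thresholds = thr, hits = hits, files = unlist(files)),
            class = "rhm_analysis")
}

#' Tabulate scan results in the reporting layout
#'
#' One row per window: id, chromosome, bp span, flanking snp ids, LRT,
#' -log10 p, regional and whole-genome heritability, convergence flag.
#' Machine precision is kept; round only for display.
#'
#' @param scan a \code{region_scan}.
#' @return data.frame ready for \code{write.table}.
#' @export
format_scan_results <- function(scan) {
  r <- scan$results
  out <- data.frame(window_id = r$window_id, chr = r$chromosome,
                    bp_start = r$bp_start, bp_end = r$bp_end,
                    first_snp = r$first_snp, last_snp = r$last_snp,
                    LRT = r$LRT, neg_log10_p = r$neg_log10_p,
                    h2_region = r$h2_region, h2_whole = r$h2_whole,
                    converged = r$converged)
  if (!is.null(r$parent_window_id)) out$parent_window_id <- r$parent_window_id
  out
}

#' @export
print.rhm_analysis <- function(x, ...) {
  cat("regional heritability analysis\n")
  cat(sprintf("  %d samples, %d SNPs after QC\n",
              x$qc_report$n_samples_out, x$qc_report$n_snps_out))
  s <- x$scan100$summary
  cat(sprintf("  whole-genome h2 %.3f (s.e. %.3f) over %d 100-SNP windows\n",
              s$h2_whole_mean, s$h2_whole_se, s$n_windows))
  cat(sprintf("  genome-wide hits: %d windows (100-SNP), %d SNPs (SSGWAS)\n",
              nrow(x$hits$window100_genomewide),
              nrow(x$hits$ssgwas_genomewide)))
  invisible(x)
}
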