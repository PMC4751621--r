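test_that("region scan returns well-formed, bounded results", {
  ana <- small_analysis()
  w <- make_windows(ana$gm$variants, 100, 50)
  sc <- scan_regions(ana$y, ana$gm, w, ana$G_w)
  r <- sc$results
  expect_equal(nrow(r), nrow(w))
  expect_true(all(r$LRT >= 0))
  expect_true(all(r$h2_region >= 0 & r$h2_region <= 1))
  expect_true(all(r$h2_whole >= 0 & r$h2_whole <= 1))
  expect_true(all(r$h2_region + r$h2_whole <= 1 + 1e-12))
  expect_true(all(abs(lrt_to_neg_log10_p(r$LRT) - r$neg_log10_p) < 1e-12))
  expect_true(is.finite(sc$summary$h2_whole_mean))
  # the injected 15% QTL region carries the scan's top LRT here
  harb <- harboring_windows(r, ana$coh$truth)
  expect_true(which.max(r$LRT) %in% harb)
})

test_that("scan is a deterministic function of its inputs", {
  ana <- small_analysis()
  w <- make_windows(ana$gm$variants, 100, 50)
  s1 <- scan_regions(ana$y, ana$gm, w, ana$G_w)
  s2 <- scan_regions(ana$y, ana$gm, w, ana$G_w)
  expect_identical(s1$results, s2$results)
})

test_that("phenotype/genotype sample mismatches are caught", {
  ana <- small_analysis()
  w <- make_windows(ana$gm$variants, 100, 50)
  ybad <- ana$y
  names(ybad)[1] <- "nobody"
  expect_error(scan_regions(ybad, ana$gm, w, ana$G_w), "do not match")
  # named but shuffled phenotypes are realigned, not misused
  yshuf <- sample(ana$y)
  s1 <- scan_regions(ana$y, ana$gm, w, ana$G_w)
  s2 <- scan_regions(yshuf, ana$gm, w, ana$G_w)
  expect_equal(s1$results$LRT, s2$results$LRT, tolerance = 1e-10)
})

test_that("fine mapping rescans the top windows at 10/5 resolution", {
  ana <- small_analysis()
  w <- make_windows(ana$gm$variants, 100, 50)
  sc <- scan_regions(ana$y, ana$gm, w, ana$G_w)
  fine <- fine_map_scan(sc, ana$y, ana$gm, ana$G_w, k = 2)
  expect_equal(nrow(fine$results), 2L * 19L)
  expect_true(all(fine$results$size == 10L))
  expect_true(all(fine$results$parent_window_id %in%
                    sc$results$window_id[order(-sc$results$LRT)][1:2]))
  # fine windows stay inside their parent's span
  for (i in seq_len(nrow(fine$results))) {
    par <- sc$results[sc$results$window_id ==
                        fine$results$parent_window_id[i], ]
    expect_gte(fine$results$start[i], par$start)
    expect_lte(fine$results$end[i], par$end)
  }
})

test_that("the full pipeline runs end to end and is byte-reproducible", {
  coh <- small_cohort()
  out1 <- file.path(tempdir(), "pipe1")
  out2 <- file.path(tempdir(), "pipe2")
  res1 <- run_full_analysis(coh$genotypes, coh$phenotype, out_dir = out1,
                            top_k = 2)
  res2 <- run_full_analysis(coh$genotypes, coh$phenotype, out_dir = out2,
                            top_k = 2)
  files <- c("phenotype.tsv", "rhm_scan100.tsv", "rhm_fine10.tsv",
             "ssgwas.tsv", "thresholds.json")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # thresholds reflect the counts of tests actually performed
  expect_equal(res1$thresholds$window100$n_tests_raw,
               nrow(res1$scan100$results))
  expect_equal(res1$thresholds$window100$genomewide,
               -log10(0.05 / (nrow(res1$scan100$results) / 2)))
  expect_equal(res1$thresholds$ssgwas$n_tests_effective,
               res1$thresholds$ssgwas$n_tests_raw)
  # published-count override reproduces the reference thresholds
  res3 <- run_full_analysis(coh$genotypes, coh$phenotype, out_dir = NULL,
                            top_k = 2,
                            paper_counts = list(ssgwas = 268651,
                                                window100 = 5373,
                                                window10 = 53732))
  expect_equal(round(res3$thresholds$ssgwas$genomewide, 2), 6.73)
  expect_equal(round(res3$thresholds$window100$genomewide, 2), 4.73)
  expect_equal(round(res3$thresholds$window10$genomewide, 2), 5.73)
})

test_that("a regional QTL is flagged at the suggestive level across seeds", {
  hits <- 0L
  for (sd in 1:10) {
    cfg <- sim_config(n_samples = 500, n_families = 75, sibship_size = 3,
                      n_chromosomes = 2, snps_per_chromosome = 500,
                      qtl_spec = list(list(chromosome = 1, window = 201:300,
                                           h2_region = 0.15, n_causal = 10,
                                           causal_maf_class = "common")),
                      h2_poly = 0.45, missing_rate = 0,
                      n_hwe_violators = 0, seed = 7000 + sd)
    coh <- simulate_cohort(cfg)
    y <- prepare_phenotype(coh$phenotype)$values
    gm <- coh$genotypes
    y <- y[gm$samples]
    G_w <- bend_psd(genomic_relationship(gm))
    w <- make_windows(gm$variants, 100, 50)
    sc <- scan_regions(y, gm, w, G_w)
    thr <- suggestive_threshold(nrow(w), halve = TRUE)
    harb <- harboring_windows(sc$results, coh$truth)
    if (any(sc$results$neg_log10_p[harb] >= thr)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
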