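# dense REML log-likelihood oracle: literal evaluation of
# -0.5 [log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2pi] with solve()/
# determinant(), independent of the package's Cholesky/profile route
oracle_loglik <- function(y, K_list, sigma2) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- diag(sigma2[length(sigma2)], n)
  for (c in seq_along(K_list)) V <- V + sigma2[c] * K_list[[c]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, logarithm = TRUE)$modulus[1] +
            log(det(XtViX)) + drop(t(y) %*% P %*% y) +
            (n - 1) * log(2 * pi))
}

sim_grm_y <- function(n, m, h2, seed) {
  set.seed(seed)
  W <- matrix(stats::rnorm(n * m), n)
  K <- tcrossprod(W) / m
  g <- W %*% stats::rnorm(m) / sqrt(m)
  y <- as.numeric(sqrt(h2) * g / stats::sd(g) +
                    stats::rnorm(n, 0, sqrt(1 - h2)))
  list(K = K, y = y)
}

test_that("with K = I only the total variance is identified, as var(y)", {
  set.seed(1)
  y <- stats::rnorm(120, 5, 2)
  fit <- fit_reml(y, diag(120))
  expect_equal(sum(fit$sigma2), stats::var(y), tolerance = 1e-6)
  expect_true(fit$degenerate)
})

test_that("restricted likelihood matches the dense oracle to 1e-8", {
  d <- sim_grm_y(80, 60, 0.5, seed = 21)
  set.seed(22)
  K2 <- tcrossprod(matrix(stats::rnorm(80 * 30), 80)) / 30
  for (s2 in list(c(0.5, 0.1, 0.6), c(1, 0.01, 0.2), c(0.05, 0.9, 1.5))) {
    expect_equal(reml_loglik(d$y, list(d$K, K2), s2),
                 oracle_loglik(d$y, list(d$K, K2), s2), tolerance = 1e-8)
  }
  # single-component form agrees too
  expect_equal(reml_loglik(d$y, list(d$K), c(0.4, 0.6)),
               oracle_loglik(d$y, list(d$K), c(0.4, 0.6)), tolerance = 1e-8)
})

test_that("single-GRM fit matches a 1-D grid-search oracle in the ratio", {
  # rank-deficient K (fewer markers than samples) keeps the optimum off the
  # h2 = 1 boundary, so the comparison is at an interior maximum
  d <- sim_grm_y(50, 40, 0.5, seed = 31)
  fit <- fit_reml(d$y, d$K)
  ratio_fit <- fit$sigma2[[1]] / fit$sigma2[[2]]
  expect_gt(ratio_fit, 0)  # interior solution under strong signal
  obj <- function(loglam) {
    lam <- exp(loglam)
    oracle_loglik(d$y, list(d$K), c(lam, 1) * fit$sigma2[[2]])
  }
  coarse <- seq(-10, 10, length.out = 400)
  l1 <- coarse[which.max(vapply(coarse, obj, numeric(1)))]
  fine <- seq(l1 - 0.1, l1 + 0.1, by = 1e-4)
  l2 <- fine[which.max(vapply(fine, obj, numeric(1)))]
  finest <- seq(l2 - 2e-4, l2 + 2e-4, by = 1e-7)
  l3 <- finest[which.max(vapply(finest, obj, numeric(1)))]
  expect_equal(ratio_fit, exp(l3), tolerance = 1e-6)
})

test_that("permuting the phenotype destroys the genetic variance", {
  ana <- small_analysis()
  fit <- fit_reml(ana$y, list(w = ana$G_w))
  set.seed(55)
  perm <- replicate(20, {
    fp <- fit_reml(sample(ana$y), list(w = ana$G_w))
    fp$sigma2[["w"]]
  })
  expect_lt(stats::median(perm), fit$sigma2[["w"]])
})

test_that("LRT is zero for self-comparison and invariant to phenotype scale", {
  ana <- small_analysis()
  Gr <- suppressWarnings(
    genomic_relationship(ana$gm, 1:50, role = "regional"))
  null1 <- fit_reml(ana$y, list(w = ana$G_w))
  full1 <- fit_reml(ana$y, list(w = ana$G_w, r = Gr))
  expect_equal(lrt(full1, full1), 0)
  l1 <- lrt(full1, null1)
  expect_gte(l1, 0)
  y2 <- 3.7 * ana$y
  l2 <- lrt(fit_reml(y2, list(w = ana$G_w, r = Gr)),
            fit_reml(y2, list(w = ana$G_w)))
  expect_equal(l1, l2, tolerance = 1e-4)
})

test_that("null-model LRT lies stochastically below chi-square(1)", {
  # y simulated under the null (whole-genome + residual only); the regional
  # component is tested on its boundary, so LRT quantiles must not exceed
  # those of a one-degree chi-square
  set.seed(77)
  n <- 120
  W <- matrix(stats::rnorm(n * 300), n)
  Gw_mat <- tcrossprod(W) / 300
  Gr_mat <- tcrossprod(W[, 1:40]) / 40
  Gw <- structure(list(values = Gw_mat), class = "grm")
  Gr <- structure(list(values = Gr_mat), class = "grm")
  ch <- chol(0.4 * Gw_mat + 0.6 * diag(n))
  stats_null <- replicate(100, {
    y <- as.numeric(crossprod(ch, stats::rnorm(n)))
    nf <- fit_reml(y, list(w = Gw))
    ff <- fit_reml(y, list(w = Gw, r = Gr),
                   start = c(max(nf$sigma2[["w"]], 0.02), 0.02,
                             max(nf$sigma2[["e"]], 0.02)))
    max(0, 2 * (ff$loglik - nf$loglik))
  })
  for (p in c(0.5, 0.9, 0.95)) {
    emp <- unname(stats::quantile(stats_null, p))
    expect_lte(emp, stats::qchisq(p, df = 1) + 0.3)
  }
  # and the chi-square(0.5) calibration is at most mildly anti-conservative
  # relative to the 50:50 boundary mixture
  p_half <- mean(lrt_to_neg_log10_p(stats_null) >= -log10(0.05))
  p_mix <- mean(lrt_to_neg_log10_p(stats_null, "mixture") >= -log10(0.05))
  expect_lte(p_half, p_mix + 0.05)
})

test_that("LRT to -log10 p mapping behaves at the edges", {
  expect_equal(lrt_to_neg_log10_p(0), 0)
  expect_error(lrt_to_neg_log10_p(-1), "non-negative")
  x <- c(0.5, 2, 10, 30)
  expect_true(all(diff(lrt_to_neg_log10_p(x)) > 0))
  expect_true(all(diff(lrt_to_neg_log10_p(x, "mixture")) > 0))
  # the fractional-df map is more significant than the mixture for large LRT
  expect_gt(lrt_to_neg_log10_p(25), lrt_to_neg_log10_p(25, "mixture"))
})

test_that("boundary components are pinned to exact zero", {
  set.seed(91)
  n <- 100
  K <- tcrossprod(matrix(stats::rnorm(n * 200), n)) / 200
  y <- stats::rnorm(n)  # no genetic signal
  fit <- fit_reml(y, list(w = K))
  expect_true(fit$sigma2[["w"]] == 0 || fit$sigma2[["w"]] < 0.05)
  if (fit$sigma2[["w"]] == 0) expect_true(fit$boundary[["w"]])
})
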