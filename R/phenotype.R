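#' Per-cohort covariate adjustment
#'
#' Fits, separately within each cohort, the ordinary least-squares model
#' \code{trait ~ intercept + sex + age + age^2} and returns the residuals.
#' Samples with a missing trait or covariate are dropped (and listed in the
#' provenance). Rank-deficient designs (e.g. a single-sex cohort) drop the
#' offending column with a warning rather than failing.
#'
#' @param table data.frame with columns \code{sample_id}, \code{cohort},
#'   \code{sex} (0/1), \code{age} (years) and the trait column.
#' @param trait name of the trait column (default \code{"trait"}).
#' @return List with \code{residuals} (named by sample_id, fitted samples
#'   only, input order), \code{fits} (per-cohort coefficient tables and n)
#'   and \code{dropped} (sample ids lost to missingness).
#' @export
adjust_covariates <- function(table, trait = "trait") {
  need <- c("sample_id", "cohort", "sex", "age", trait)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("trait table lacks columns: ",
                         paste(miss, collapse = ", "))
  table <- as.data.frame(table)
  y <- table[[trait]]
  ok <- !(is.na(y) | is.na(table$sex) | is.na(table$age))
  dropped <- table$sample_id[!ok]
  tab <- table[ok, , drop = FALSE]
  y <- y[ok]

  res <- rep(NA_real_, nrow(tab))
  fits <- list()
  for (ch in unique(tab$cohort)) {
    idx <- which(tab$cohort == ch)
    if (length(idx) < 5)
      stop("cohort ", ch, " has fewer than 5 usable samples")
    X <- cbind(intercept = 1, sex = tab$sex[idx], age = tab$age[idx],
               age2 = tab$age[idx]^2)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      warning("cohort ", ch, ": dropping rank-deficient column(s) ",
              paste(colnames(X)[-keep], collapse = ", "))
      X <- X[, keep, drop = FALSE]
      qrX <- qr(X)
    }
    beta <- qr.coef(qrX, y[idx])
    res[idx] <- y[idx] - X %*% beta
    fits[[as.character(ch)]] <- list(coefficients = beta, n = length(idx))
  }
  names(res) <- tab$sample_id
  list(residuals = res, fits = fits, dropped = dropped)
}

#' Rank inverse-normal transform
#'
#' Maps values to standard-normal quantiles by rank:
#' \code{qnorm((rank - offset) / (n - 2*offset + 1))}. The default
#' \code{offset = 0.5} gives \code{qnorm((rank - 0.5)/n)}; \code{offset =
#' 3/8} is the Blom variant. Ties receive the average rank, so the transform
#' is deterministic and permutation-invariant.
#'
#' @param x numeric vector, n >= 2.
#' @param offset rank offset c in \code{(rank - c)/(n - 2c + 1)}.
#' @return Standard-normal scores in the input order.
#' @examples
#' rank_inverse_normal(c(3, 1, 2))  # qnorm(c(5, 1, 3)/6)
#' @export
rank_inverse_normal <- function(x, offset = 0.5) {
  if (length(x) < 2) stop("need at least 2 values to rank")
  if (anyNA(x)) stop("missing values not allowed; drop them upstream")
  if (length(unique(x)) == 1)
    stop("all values identical: no ordering information")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (length(x) - 2 * offset + 1))
}

#' Build the analysis phenotype
#'
#' The standard preparation for mixed-model association in merged cohorts:
#' within each cohort, adjust the trait for sex, age and age squared by OLS,
#' rank-transform the residuals to the standard normal, then concatenate the
#' cohorts. The adjusted and rank-transformed values are the phenotype used
#' by both the regional scan and the single-SNP scan.
#'
#' @inheritParams adjust_covariates
#' @param offset rank offset passed to [rank_inverse_normal()].
#' @return List with \code{values} (named standard-normal scores, input
#'   sample order, missing-covariate samples omitted) and \code{provenance}
#'   (per-cohort fit summaries and dropped ids).
#' @export
prepare_phenotype <- function(table, trait = "trait", offset = 0.5) {
  adj <- adjust_covariates(table, trait = trait)
  tab <- as.data.frame(table)
  tab <- tab[match(names(adj$residuals), tab$sample_id), , drop = FALSE]
  z <- rep(NA_real_, length(adj$residuals))
  for (ch in unique(tab$cohort)) {
    idx <- which(tab$cohort == ch)
    z[idx] <- rank_inverse_normal(adj$residuals[idx], offset = offset)
  }
  names(z) <- names(adj$residuals)
  list(values = z,
       provenance = list(fits = adj$fits, dropped = adj$dropped,
                         offset = offset))
}
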