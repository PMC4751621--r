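#' Construct a genotype matrix object
#'
#' The central genotype container: an \code{n_samples x m_snps} numeric matrix
#' of allele-B dosages coded \code{0} (AA), \code{0.5} (AB) and \code{1} (BB),
#' with \code{NA} for missing calls, plus a variant registry and sample ids.
#' The 0/0.5/1 coding puts dosages directly on the allele-fraction scale, so
#' the mean dosage of a SNP is its allele-B frequency.
#'
#' @param values numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 0.5, 1 or NA.
#' @param variants data.frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position}, \code{allele_a}, \code{allele_b}; one row per column of
#'   \code{values}. Positions are 1-based.
#' @param samples character vector of sample ids, one per row of
#'   \code{values}.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{values}, \code{variants}, \code{samples}.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0, 0.5, 1, 1), 2, 2),
#'   variants = data.frame(snp_id = c("s1", "s2"), chromosome = 1L,
#'                         position = c(100L, 200L),
#'                         allele_a = "A", allele_b = "B"),
#'   samples = c("id1", "id2"))
#' allele_frequency(gm, 1)
#' @export
genotype_matrix <- function(values, variants, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.data.frame(variants)) stop("variants must be a data.frame")
  need <- c("snp_id", "chromosome", "position", "allele_a", "allele_b")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(values))
    stop("variants has ", nrow(variants), " rows but values has ",
         ncol(values), " columns")
  if (length(samples) != nrow(values))
    stop("samples has length ", length(samples), " but values has ",
         nrow(values), " rows")
  if (anyDuplicated(variants$snp_id)) stop("snp_id values must be unique")
  bad <- values[!is.na(values)]
  if (length(bad) && !all(bad %in% c(0, 0.5, 1)))
    stop("genotype dosages must be 0, 0.5, 1 or NA")
  variants <- as.data.frame(variants)[, need]
  variants$chromosome <- as.integer(variants$chromosome)
  variants$position <- as.integer(variants$position)
  rownames(variants) <- NULL
  dimnames(values) <- list(as.character(samples), variants$snp_id)
  structure(list(values = values, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$variants$chromosome), collapse = " "),
      "\n")
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x a \code{genotype_matrix}.
#' @param samples row (sample) index vector, or NULL for all.
#' @param snps column (SNP) index vector, or NULL for all.
#' @return A \code{genotype_matrix} restricted to the given rows/columns.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(samples)) samples <- seq_along(x$samples)
  if (is.null(snps)) snps <- seq_len(nrow(x$variants))
  if (anyNA(samples) || anyNA(snps))
    stop("NA in subset indices (unmatched sample or snp id?)")
  genotype_matrix(x$values[samples, snps, drop = FALSE],
                  x$variants[snps, , drop = FALSE],
                  x$samples[samples])
}

#' Allele-B frequency of one SNP
#'
#' The mean dosage over non-missing samples. With the 0/0.5/1 coding this is
#' exactly the frequency of allele B in the genotyped sample.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param snp column index or snp_id of one SNP.
#' @return Allele-B frequency in [0, 1].
#' @export
allele_frequency <- function(genotypes, snp) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$values[, snp]
  if (all(is.na(g))) stop("SNP ", snp, " has no non-missing calls")
  mean(g, na.rm = TRUE)
}

#' Allele-B frequencies of all SNPs
#'
#' Vectorized form of [allele_frequency()]; SNPs with no non-missing call get
#' NA (callers decide how to handle them).
#'
#' @param genotypes a \code{genotype_matrix}.
#' @return Numeric vector of per-SNP allele-B frequencies.
#' @export
allele_frequencies <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  colMeans(genotypes$values, na.rm = TRUE)
}

#' Per-SNP and per-sample call rates
#'
#' @param genotypes a \code{genotype_matrix}.
#' @return List with \code{snp} and \code{sample} call-rate vectors.
#' @export
call_rates <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ok <- !is.na(genotypes$values)
  list(snp = colMeans(ok), sample = rowMeans(ok))
}

#' Write genotypes as a plain-text dosage table
#'
#' TSV dialect: header \code{sample_id} followed by snp ids; cells in
#' \{0, 0.5, 1, NA\}. Variant coordinates travel in a side-car
#' \code{<file>.variants} TSV so the table round-trips to a full
#' \code{genotype_matrix}.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param file output path for the dosage TSV.
#' @return \code{file}, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, file) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(sample_id = genotypes$samples,
                   genotypes$values, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genotypes$variants, paste0(file, ".variants"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a plain-text dosage table
#'
#' @param file path written by [write_dosage_tsv()].
#' @return A \code{genotype_matrix}.
#' @export
read_dosage_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  vfile <- paste0(file, ".variants")
  if (!file.exists(vfile)) stop("variant side-car not found: ", vfile)
  variants <- utils::read.table(vfile, sep = "\t", header = TRUE,
                                colClasses = c("character", "integer",
                                               "integer", "character",
                                               "character"))
  samples <- df$sample_id
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  genotype_matrix(vals, variants, samples)
}
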