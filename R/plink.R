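#' Read a PLINK binary genotype triplet
#'
#' Reads \code{<prefix>.bed/.bim/.fam} (bed v1.00 magic \code{0x6c 0x1b
#' 0x01}, SNP-major). The counted allele is the first allele column of the
#' .bim file (the "B" allele), so the two-bit codes map to dosages as:
#' \code{00} (hom first allele) -> 1, \code{10} (het) -> 0.5, \code{11}
#' (hom second allele) -> 0 and \code{01} -> missing.
#'
#' @param prefix path prefix of the .bed/.bim/.fam triplet.
#' @return A \code{genotype_matrix}.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)

  bimdf <- utils::read.table(bim, col.names = c("chromosome", "snp_id", "cm",
                                                "position", "a1", "a2"),
                             colClasses = c("integer", "character", "numeric",
                                            "integer", "character",
                                            "character"))
  famdf <- utils::read.table(fam, colClasses = "character")
  samples <- famdf[[2]]
  n <- length(samples)
  m <- nrow(bimdf)

  raw <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic at byte offset 0): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("PLINK .bed not in SNP-major mode (byte offset 2): ", bed)
  bps <- ceiling(n / 4)  # bytes per SNP
  expect <- 3 + bps * m
  if (length(raw) != expect)
    stop("PLINK .bed has ", length(raw), " bytes, expected ", expect,
         " (mismatch from byte offset ", min(length(raw), expect), ")")

  body <- raw[-(1:3)]
  ints <- as.integer(body)                       # one int per byte
  codes <- matrix(0L, nrow = 4 * bps, ncol = m)  # 2-bit codes, padded rows
  shift <- c(1L, 4L, 16L, 64L)
  for (s in 1:4) {
    codes[seq(s, 4 * bps, by = 4), ] <- (ints %/% shift[s]) %% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 1 (hom counted allele), 10 -> 0.5, 11 -> 0, 01 -> NA
  vals <- matrix(NA_real_, n, m)
  vals[codes == 0L] <- 1
  vals[codes == 2L] <- 0.5
  vals[codes == 3L] <- 0

  variants <- data.frame(snp_id = bimdf$snp_id, chromosome = bimdf$chromosome,
                         position = bimdf$position, allele_a = bimdf$a2,
                         allele_b = bimdf$a1)
  genotype_matrix(vals, variants, samples)
}

#' Write a PLINK binary genotype triplet
#'
#' Inverse of [read_plink()]: emits \code{<prefix>.bed} (v1.00 SNP-major),
#' \code{<prefix>.bim} with the counted (B) allele in the first allele column
#' and \code{<prefix>.fam} with unknown parents/sex.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  n <- length(genotypes$samples)
  m <- nrow(v)

  utils::write.table(
    data.frame(v$chromosome, v$snp_id, 0, v$position, v$allele_b, v$allele_a),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(genotypes$samples, genotypes$samples, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 1 -> 00, 0.5 -> 10, 0 -> 11, NA -> 01
  codes <- matrix(1L, n, m)
  x <- genotypes$values
  codes[!is.na(x) & x == 1] <- 0L
  codes[!is.na(x) & x == 0.5] <- 2L
  codes[!is.na(x) & x == 0] <- 3L
  bps <- ceiling(n / 4)
  pad <- 4 * bps - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, m))
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, bps, m)
  for (s in 1:4) {
    bytes <- bytes + codes[seq(s, 4 * bps, by = 4), , drop = FALSE] * shift[s]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}
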