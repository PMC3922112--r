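#' Genotype matrix container
#'
#' A light container for an n individuals x m SNPs dosage matrix in
#' {0, 1, 2, NA}, where the dosage counts copies of the A1 (reference) allele,
#' together with sample identifiers and per-SNP metadata.
#'
#' @param dosage Numeric or integer n x m matrix with values in
#'   {0, 1, 2, NA}.
#' @param snps Optional data frame with columns \code{id}, \code{chr},
#'   \code{pos}, \code{a1}, \code{a2} (one row per SNP); generated if absent.
#' @param sample_ids Optional character vector of unique sample identifiers;
#'   generated if absent.
#' @return An object of class \code{"genotype_matrix"}: a list with elements
#'   \code{dosage}, \code{sample_ids}, \code{snps}.
#' @export
genotype_matrix <- function(dosage, snps = NULL, sample_ids = NULL) {
  if (!is.matrix(dosage)) stopf("`dosage` must be a matrix")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stopf("dosages must be 0, 1, 2 or NA")
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(sample_ids)) sample_ids <- sprintf("id%05d", seq_len(n))
  if (length(sample_ids) != n) stopf("need one sample id per row")
  if (anyDuplicated(sample_ids)) stopf("sample ids must be unique")
  if (is.null(snps)) {
    ids <- if (!is.null(colnames(dosage))) colnames(dosage)
           else sprintf("snp%04d", seq_len(m))
    snps <- data.frame(id = ids, chr = rep(1L, m), pos = seq_len(m),
                       a1 = rep("A", m), a2 = rep("B", m),
                       stringsAsFactors = FALSE)
  }
  if (nrow(snps) != m) stopf("need one snp record per column")
  if (anyDuplicated(snps$id)) stopf("snp ids must be unique")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_ids, snps$id)
  structure(list(dosage = dosage, sample_ids = as.character(sample_ids),
                 snps = snps),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# PLINK 1 binary: magic bytes then SNP-major 2-bit codes, 4 samples/byte,
# first sample in the lowest-order bit pair.
#   00 -> 2 copies of A1, 10 -> 1 copy, 11 -> 0 copies, 01 -> missing
PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
CODE_TO_DOSAGE <- c(2L, NA_integer_, 1L, 0L)       # index = code + 1
DOSAGE_TO_CODE <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # missing -> 1

#' Read PLINK 1 binary genotypes
#'
#' Reads \code{<prefix>.bed/.bim/.fam}. Dosages count the A1 allele of the
#' .bim file; missing genotypes become \code{NA}. Row and column order follow
#' the .fam and .bim files.
#'
#' @param prefix Path prefix of the fileset.
#' @return A list with \code{genotypes} (a \code{\link{genotype_matrix}}) and
#'   \code{samples}, a stub sample table from the .fam file (columns
#'   \code{FID}, \code{IID}, \code{SEX_CODE}, \code{PHENO}).
#' @seealso \code{\link{write_plink}}
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stopf("PLINK file not found: %s", p)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("FID", "IID", "PID", "MID", "SEX_CODE",
                                  "PHENO"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:2], PLINK_MAGIC[1:2]))
    stopf("%s: not a PLINK .bed file (bad magic bytes)", paths[1])
  if (raw[3] != PLINK_MAGIC[3])
    stopf("%s: only SNP-major .bed files are supported", paths[1])
  bpl <- ceiling(n / 4)
  if (length(raw) - 3L != bpl * m)
    stopf("%s: truncated or oversized payload (expected %d data bytes, found %d)",
          paths[1], bpl * m, length(raw) - 3L)
  bytes <- as.integer(raw[-(1:3)])
  # decode all 4 bit-pairs of every byte, then trim padding rows
  codes <- rbind(bitwAnd(bytes, 3L),
                 bitwAnd(bitwShiftR(bytes, 2L), 3L),
                 bitwAnd(bitwShiftR(bytes, 4L), 3L),
                 bitwAnd(bitwShiftR(bytes, 6L), 3L))
  dim(codes) <- c(4L * bpl, m)
  d <- matrix(CODE_TO_DOSAGE[codes[seq_len(n), , drop = FALSE] + 1L],
              nrow = n, ncol = m)
  snps <- bim[, c("id", "chr", "pos", "a1", "a2")]
  list(genotypes = genotype_matrix(d, snps = snps, sample_ids = fam$IID),
       samples = fam[, c("FID", "IID", "SEX_CODE", "PHENO")])
}

#' Write PLINK 1 binary genotypes
#'
#' Writes \code{<prefix>.bed} (SNP-major, zero padding bits), \code{.bim} and
#' \code{.fam}. Inverse of \code{\link{read_plink}} on the dosage matrix and
#' SNP metadata.
#'
#' @param G A \code{\link{genotype_matrix}}.
#' @param prefix Output path prefix.
#' @param fam Optional data frame with columns \code{FID}, \code{IID},
#'   \code{PID}, \code{MID}, \code{SEX_CODE}, \code{PHENO}; defaults to a
#'   minimal table built from the sample ids.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(G, prefix, fam = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosage)
  m <- ncol(G$dosage)
  if (n == 0L || m == 0L) stopf("cannot write an empty genotype matrix")
  if (is.null(fam)) {
    fam <- data.frame(FID = G$sample_ids, IID = G$sample_ids, PID = 0L,
                      MID = 0L, SEX_CODE = 0L, PHENO = -9L)
  }
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  bim <- data.frame(chr = G$snps$chr, id = G$snps$id, cm = 0L,
                    pos = G$snps$pos, a1 = G$snps$a1, a2 = G$snps$a2)
  write.table(bim, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(fam, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bpl <- ceiling(n / 4)
  codes <- matrix(1L, nrow = 4L * bpl, ncol = m)       # default: missing
  d <- G$dosage
  code <- matrix(1L, nrow = n, ncol = m)
  code[!is.na(d)] <- DOSAGE_TO_CODE[as.character(d[!is.na(d)])]
  codes[seq_len(n), ] <- code
  codes[seq_len(4L * bpl) > n, ] <- 0L                 # padding bits zero
  bytes <- codes[seq(1L, 4L * bpl, by = 4L), , drop = FALSE] +
    4L  * codes[seq(2L, 4L * bpl, by = 4L), , drop = FALSE] +
    16L * codes[seq(3L, 4L * bpl, by = 4L), , drop = FALSE] +
    64L * codes[seq(4L, 4L * bpl, by = 4L), , drop = FALSE]
  con <- file(paths[1], "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(paths)
}
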