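#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' probability of every heterozygote count with the same allele total is
#' computed under the HWE sampling distribution, and the p-value is the sum
#' of probabilities of all tables whose conditional probability does not
#' exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa Observed genotype counts (nonnegative, total >= 1).
#' @return The exact p-value in (0, 1].
#' @examples
#' hwe_exact_p(25, 50, 25)   # modal table: p = 1
#' hwe_exact_p(50, 0, 50)    # extreme heterozygote deficit
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (!is_count(n_AA) || !is_count(n_Aa) || !is_count(n_aa))
    stopf("genotype counts must be nonnegative integers")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stopf("HWE test undefined for all-zero genotype counts")
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)   # monomorphic: single possible table
  # heterozygote counts sharing the allele total (and its parity)
  h <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((2 * n - nA - h) / 2) + h * log(2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_Aa, h)]
  sum(prob[prob <= obs * (1 + 1e-10)])
}

#' Marker quality control
#'
#' Removes SNPs with missing call fraction above \code{miss_max}, minor
#' allele frequency below \code{maf_min}, or Hardy-Weinberg exact p-value
#' below \code{hwe_min}, in that fixed order; a SNP is attributed to the
#' first filter that removes it. Allele frequencies and HWE are computed on
#' non-missing genotypes; monomorphic SNPs are removed by the MAF filter.
#' The sample set is unchanged.
#'
#' @param G A \code{\link{genotype_matrix}}.
#' @param miss_max Maximum tolerated missing fraction (exclusive; a SNP is
#'   removed when its missing fraction is strictly greater). Default 0.05.
#' @param maf_min Minimum minor allele frequency (SNPs with MAF strictly
#'   below are removed). Default 0.01.
#' @param hwe_min Minimum HWE exact p-value (strictly below removes).
#'   Default 1e-6.
#' @return A list with \code{genotypes} (the filtered matrix) and
#'   \code{report}, a \code{"qc_report"} with per-filter removal counts.
#' @examples
#' G <- simulate_genotypes(sim_config(100, 50, seed = 3))
#' qc <- qc_filter(G)
#' qc$report
#' @export
qc_filter <- function(G, miss_max = 0.05, maf_min = 0.01, hwe_min = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  for (th in c(miss_max, maf_min, hwe_min))
    if (!is_prob(th)) stopf("QC thresholds must lie in [0, 1]")
  d <- G$dosage
  m <- ncol(d)
  miss <- colMeans(is.na(d))
  nobs <- colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * pmax(nobs, 1L))
  maf <- pmin(freq, 1 - freq)
  maf[nobs == 0L] <- 0
  drop_miss <- miss > miss_max
  drop_maf <- !drop_miss & (maf < maf_min)
  candidate <- which(!drop_miss & !drop_maf)
  drop_hwe <- logical(m)
  if (length(candidate) > 0 && hwe_min > 0) {
    nAA <- colSums(d[, candidate, drop = FALSE] == 2, na.rm = TRUE)
    nAa <- colSums(d[, candidate, drop = FALSE] == 1, na.rm = TRUE)
    naa <- colSums(d[, candidate, drop = FALSE] == 0, na.rm = TRUE)
    hp <- vapply(seq_along(candidate),
                 function(i) hwe_exact_p(nAA[i], nAa[i], naa[i]),
                 numeric(1))
    drop_hwe[candidate] <- hp < hwe_min
  }
  keep <- !(drop_miss | drop_maf | drop_hwe)
  if (!any(keep)) stopf("quality control removed every SNP")
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         snps = G$snps[keep, , drop = FALSE],
                         sample_ids = G$sample_ids)
  attr(out, "true_freq") <- attr(G, "true_freq")[keep]
  report <- structure(list(
    n_input = m,
    removed = c(missingness = sum(drop_miss), maf = sum(drop_maf),
                hwe = sum(drop_hwe)),
    retained = sum(keep),
    thresholds = c(miss_max = miss_max, maf_min = maf_min,
                   hwe_min = hwe_min)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker quality control\n")
  cat(sprintf("  input SNPs: %d\n", x$n_input))
  cat(sprintf("  removed: %d by missingness (> %.3g), %d by MAF (< %.3g), %d by HWE (p < %.3g)\n",
              x$removed[["missingness"]], x$thresholds[["miss_max"]],
              x$removed[["maf"]], x$thresholds[["maf_min"]],
              x$removed[["hwe"]], x$thresholds[["hwe_min"]]))
  cat(sprintf("  retained: %d\n", x$retained))
  invisible(x)
}

#' Write a QC report as tab-separated text
#'
#' @param report A \code{"qc_report"}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_input", "removed_missingness", "removed_maf",
               "removed_hwe", "retained", "miss_max", "maf_min", "hwe_min"),
    value = c(report$n_input, report$removed, report$retained,
              report$thresholds)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
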