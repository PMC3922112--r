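# Per-SNP two-environment interaction scan: within each environment an
# ordinary least-squares regression of the adjusted phenotype on dosage, then
# a slope-difference z test (PLINK GxE convention, normal reference).

# Closed-form simple regression of y on each column of D within one stratum.
# Returns per-SNP n, slope, and slope SE; SNPs with < 3 informative samples
# or constant dosage get NA.
stratum_ols <- function(D, y) {
  obs <- !is.na(D) & !is.na(y)
  Dz <- D
  Dz[!obs] <- 0
  yz <- ifelse(is.na(y), 0, y)
  nobs <- colSums(obs)
  Sx <- colSums(Dz)
  Sy <- colSums(yz * obs)
  Sxx <- colSums(Dz^2) - Sx^2 / pmax(nobs, 1)
  Sxy <- colSums(Dz * yz) - Sx * Sy / pmax(nobs, 1)
  Syy <- colSums(yz^2 * obs) - Sy^2 / pmax(nobs, 1)
  ok <- nobs >= 3 & Sxx > 1e-12
  b <- ifelse(ok, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - b * Sxy, 0)
  se <- ifelse(ok, sqrt(rss / (nobs - 2) / Sxx), NA_real_)
  list(n = nobs, b = b, se = se, ok = ok)
}

#' Per-SNP genotype-environment interaction test
#'
#' Within each of two environment levels, ordinary least squares of the
#' phenotype on the SNP dosage gives a slope and standard error
#' \eqn{(b_1, se_1)} and \eqn{(b_2, se_2)}; the interaction statistic is
#' \deqn{z = (b_1 - b_2) / \sqrt{se_1^2 + se_2^2}} with a two-sided normal
#' p-value. The pooled main-effect p-value comes from the single-regression
#' slope t-test on all samples.
#'
#' @param dosage Numeric vector of dosages in {0, 1, 2, NA}.
#' @param y Adjusted phenotype vector, same length.
#' @param env Factor with exactly two levels.
#' @return A one-row data frame with slopes, standard errors,
#'   per-environment sample sizes, \code{Z}, \code{P_GXE} and \code{P_G}.
#'   Monomorphic dosage within a level flags the record (\code{P_GXE = NA}).
#' @examples
#' set.seed(1)
#' d <- rbinom(200, 2, 0.4)
#' e <- factor(rep(1:2, each = 100))
#' y <- ifelse(e == 1, 0.5, -0.5) * d + rnorm(200)
#' snp_gxe_test(d, y, e)
#' @export
snp_gxe_test <- function(dosage, y, env) {
  env <- as.factor(env)
  if (nlevels(env) != 2L) stopf("the scan needs exactly two environment levels")
  if (length(dosage) != length(y) || length(y) != length(env))
    stopf("`dosage`, `y` and `env` must have equal length")
  D <- matrix(dosage, ncol = 1)
  lev <- levels(env)
  s1 <- stratum_ols(D[env == lev[1], , drop = FALSE], y[env == lev[1]])
  s2 <- stratum_ols(D[env == lev[2], , drop = FALSE], y[env == lev[2]])
  sp <- stratum_ols(D, y)
  z <- (s1$b - s2$b) / sqrt(s1$se^2 + s2$se^2)
  p <- 2 * pnorm(-abs(z))
  t_g <- sp$b / sp$se
  p_g <- 2 * pt(-abs(t_g), df = pmax(sp$n - 2, 1))
  data.frame(N1 = s1$n, B1 = s1$b, SE1 = s1$se,
             N2 = s2$n, B2 = s2$b, SE2 = s2$se,
             Z = z, P_GXE = p, P_G = p_g)
}

#' Genome-wide two-environment interaction scan
#'
#' Applies \code{\link{snp_gxe_test}} to every SNP of a genotype matrix
#' (vectorized), returning records sorted by interaction p-value. SNPs that
#' are monomorphic or under-observed within a level are retained with
#' missing p-values.
#'
#' @param G A \code{\link{genotype_matrix}} (post-QC).
#' @param y Adjusted phenotype vector, named by sample id or aligned with
#'   the genotype rows.
#' @param env Environment factor with exactly two levels, named or aligned.
#' @param report_threshold P-value below which SNPs are counted in the
#'   summary attribute (default 0.001).
#' @return A data frame with columns \code{SNP}, \code{CHR}, \code{POS},
#'   \code{N1}, \code{B1}, \code{SE1}, \code{N2}, \code{B2}, \code{SE2},
#'   \code{Z}, \code{P_GXE}, \code{P_G}, sorted by \code{P_GXE}; the number
#'   of SNPs below \code{report_threshold} is attached as attribute
#'   \code{"n_below_threshold"}.
#' @export
gxe_scan <- function(G, y, env, report_threshold = 0.001) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (ncol(G$dosage) == 0L) stopf("no SNPs to scan")
  ids <- G$sample_ids
  if (!is.null(names(y))) y <- y[ids]
  if (length(y) != length(ids)) stopf("`y` must align with the genotype rows")
  env <- align_env(env, ids)
  if (nlevels(env) != 2L) stopf("the scan needs exactly two environment levels")
  lev <- levels(env)
  D <- G$dosage
  s1 <- stratum_ols(D[env == lev[1], , drop = FALSE], y[env == lev[1]])
  s2 <- stratum_ols(D[env == lev[2], , drop = FALSE], y[env == lev[2]])
  sp <- stratum_ols(D, y)
  z <- (s1$b - s2$b) / sqrt(s1$se^2 + s2$se^2)
  p <- 2 * pnorm(-abs(z))
  t_g <- sp$b / sp$se
  p_g <- 2 * pt(-abs(t_g), df = pmax(sp$n - 2, 1))
  out <- data.frame(SNP = G$snps$id, CHR = G$snps$chr, POS = G$snps$pos,
                    N1 = s1$n, B1 = s1$b, SE1 = s1$se,
                    N2 = s2$n, B2 = s2$b, SE2 = s2$se,
                    Z = z, P_GXE = p, P_G = p_g,
                    stringsAsFactors = FALSE)
  out <- out[order(out$P_GXE, method = "radix", na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "n_below_threshold") <- sum(out$P_GXE < report_threshold,
                                        na.rm = TRUE)
  attr(out, "report_threshold") <- report_threshold
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_tests Number of tests in the family (>= 1).
#' @return \code{alpha / n_tests}.
#' @examples
#' bonferroni_threshold(0.05, 147)  # 49 traits x 3 environmental factors
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must lie in (0, 1)")
  if (!is_count(n_tests) || n_tests < 1)
    stopf("`n_tests` must be a positive integer")
  alpha / n_tests
}
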