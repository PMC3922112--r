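#' Genetic relationship matrix container
#'
#' @param values Symmetric n x n numeric matrix of realized relationships.
#' @param sample_ids Character vector matching the row/column order.
#' @param n_snps Per-pair count of SNPs used (matrix), or a single count when
#'   no genotypes were missing.
#' @return An object of class \code{"grm_matrix"}.
#' @export
grm_matrix <- function(values, sample_ids, n_snps = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stopf("`values` must be a square matrix")
  if (max(abs(values - t(values))) > 1e-12)
    stopf("`values` must be symmetric within 1e-12")
  if (length(sample_ids) != nrow(values))
    stopf("`sample_ids` must match the matrix dimension")
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 n_snps = n_snps),
            class = "grm_matrix")
}

#' @export
print.grm_matrix <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("GRM: %d individuals; mean diagonal %.4f; off-diagonal range [%.4f, %.4f]\n",
              n, mean(diag(x$values)),
              if (n > 1) min(off) else NA, if (n > 1) max(off) else NA))
  invisible(x)
}

#' @export
dim.grm_matrix <- function(x) dim(x$values)

#' Compute the realized genetic relationship matrix
#'
#' Estimates, for every pair of individuals j, k (including j = k),
#' \deqn{A_{jk} = \frac{1}{N_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)},}
#' where \eqn{x_{ij}} counts copies of the reference (A1) allele, \eqn{p_i}
#' is its sample frequency, and the sum runs over the \eqn{N_{jk}} SNPs
#' non-missing in both individuals. The diagonal uses the same formula as
#' the off-diagonal. SNPs that are monomorphic in the sample are excluded
#' with a warning.
#'
#' @param G A \code{\link{genotype_matrix}} (post-QC).
#' @return A \code{\link{grm_matrix}}.
#' @examples
#' G <- simulate_genotypes(sim_config(100, 500, seed = 4))
#' A <- compute_grm(G)
#' mean(diag(A$values))
#' @export
compute_grm <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  nobs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(nobs, 1L))
  poly <- nobs > 0 & p > 0 & p < 1
  if (!any(poly)) stopf("no polymorphic SNPs available for the GRM")
  if (any(!poly))
    warnf("excluding %d monomorphic SNP(s) from the GRM", sum(!poly))
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(d, 2L, 2 * p, "-")
  w <- sweep(w, 2L, sqrt(2 * p * (1 - p)), "/")
  has_na <- anyNA(d)
  if (has_na) {
    obs <- (!is.na(d)) * 1
    w[is.na(w)] <- 0
    N <- tcrossprod(obs)
    if (any(N == 0))
      stopf("some pairs share no non-missing SNPs; cannot form the GRM")
    values <- tcrossprod(w) / N
    n_snps <- N
  } else {
    values <- tcrossprod(w) / ncol(d)
    n_snps <- ncol(d)
  }
  values <- (values + t(values)) / 2
  grm_matrix(values, G$sample_ids, n_snps = n_snps)
}

#' Prune related individuals from a GRM
#'
#' Greedy hub-first removal: while any retained pair has an estimated
#' relationship strictly above \code{cutoff}, drop the individual currently
#' involved in the largest number of above-cutoff pairs (on ties the
#' earliest-listed individual is kept and the latest dropped). Removing the
#' most-connected individual first retains the largest possible set of
#' mutually "unrelated" individuals under the rule.
#'
#' @param A A \code{\link{grm_matrix}}.
#' @param cutoff Relatedness threshold (default 0.025).
#' @return Character vector of retained sample ids, in input order.
#' @examples
#' G <- simulate_genotypes(sim_config(60, 400, seed = 5))
#' A <- compute_grm(G)
#' keep <- prune_related(A, cutoff = 0.1)
#' @export
prune_related <- function(A, cutoff = 0.025) {
  stopifnot(inherits(A, "grm_matrix"))
  if (!is.numeric(cutoff) || cutoff < 0) stopf("`cutoff` must be >= 0")
  v <- A$values
  n <- nrow(v)
  adj <- v > cutoff
  diag(adj) <- FALSE
  active <- rep(TRUE, n)
  repeat {
    counts <- rowSums(adj[, active, drop = FALSE]) * active
    if (max(counts) == 0) break
    tied <- which(counts == max(counts))
    drop_i <- tied[length(tied)]   # keep earlier samples on ties
    active[drop_i] <- FALSE
    adj[drop_i, ] <- FALSE
    adj[, drop_i] <- FALSE
  }
  if (sum(active) == 0)
    stopf("pruning at cutoff %.3g removed every individual", cutoff)
  if (sum(active) < 2)
    warnf("pruning at cutoff %.3g leaves fewer than 2 individuals", cutoff)
  A$sample_ids[active]
}

#' Environment-masked interaction GRM
#'
#' Builds the covariance structure of the genotype-environment interaction
#' effects: \eqn{A_{ge}} equals the additive GRM for pairs of individuals in
#' the same environment (including the diagonal) and 0 for pairs in different
#' environments.
#'
#' @param A A \code{\link{grm_matrix}}.
#' @param env Factor of environment levels, named by (or aligned with) the
#'   GRM sample ids.
#' @return A \code{\link{grm_matrix}} with the masked values.
#' @export
gxe_grm <- function(A, env) {
  stopifnot(inherits(A, "grm_matrix"))
  env <- align_env(env, A$sample_ids)
  same <- outer(env, env, "==")
  grm_matrix(A$values * same, A$sample_ids, n_snps = A$n_snps)
}

# Align an environment factor to a set of sample ids, erroring on gaps.
align_env <- function(env, ids) {
  env <- as.factor(env)
  if (!is.null(names(env))) {
    if (!all(ids %in% names(env)))
      stopf("environment level missing for %d sample(s)",
            sum(!ids %in% names(env)))
    env <- env[ids]
  } else if (length(env) != length(ids)) {
    stopf("`env` must be named by sample id or aligned with the GRM order")
  }
  if (anyNA(env)) stopf("environment level missing for some samples")
  droplevels(env)
}

#' Subset a GRM to a set of samples
#'
#' @param A A \code{\link{grm_matrix}}.
#' @param ids Sample ids to keep (order preserved as given).
#' @return The subsetted \code{\link{grm_matrix}}.
#' @export
subset_grm <- function(A, ids) {
  stopifnot(inherits(A, "grm_matrix"))
  if (!all(ids %in% A$sample_ids)) stopf("unknown sample id(s) in subset")
  idx <- match(ids, A$sample_ids)
  ns <- if (is.matrix(A$n_snps)) A$n_snps[idx, idx, drop = FALSE] else A$n_snps
  grm_matrix(A$values[idx, idx, drop = FALSE], A$sample_ids[idx], n_snps = ns)
}

#' Write a GRM in GCTA text format
#'
#' Writes \code{<prefix>.grm.gz} (tab-separated lower triangle including the
#' diagonal: 1-based indices j >= k, the per-pair SNP count, and the
#' relationship) and \code{<prefix>.grm.id} (family and individual id).
#'
#' @param A A \code{\link{grm_matrix}}.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_grm <- function(A, prefix) {
  stopifnot(inherits(A, "grm_matrix"))
  n <- nrow(A$values)
  j <- rep(seq_len(n), seq_len(n))
  k <- sequence(seq_len(n))
  nsnp <- if (is.matrix(A$n_snps)) A$n_snps[cbind(j, k)]
          else rep(if (is.null(A$n_snps)) NA_integer_ else A$n_snps,
                   length(j))
  df <- data.frame(j = j, k = k, n = nsnp, a = A$values[cbind(j, k)])
  gz <- gzfile(paste0(prefix, ".grm.gz"), "w")
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              gz, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(gz)
  write.table(data.frame(A$sample_ids, A$sample_ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".grm.gz", ".grm.id")))
}

#' Read a GRM from GCTA text format
#'
#' @param prefix Path prefix of \code{.grm.gz} / \code{.grm.id} files.
#' @return A \code{\link{grm_matrix}}.
#' @export
read_grm <- function(prefix) {
  idp <- paste0(prefix, ".grm.id")
  gzp <- paste0(prefix, ".grm.gz")
  for (p in c(idp, gzp)) if (!file.exists(p)) stopf("GRM file not found: %s", p)
  ids <- read.table(idp, header = FALSE, stringsAsFactors = FALSE)[[2]]
  df <- read.table(gzfile(gzp), header = FALSE,
                   col.names = c("j", "k", "n", "a"))
  n <- length(ids)
  v <- matrix(0, n, n)
  v[cbind(df$j, df$k)] <- df$a
  v[cbind(df$k, df$j)] <- df$a
  ns <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ns[cbind(df$j, df$k)] <- df$n
  ns[cbind(df$k, df$j)] <- df$n
  if (!anyNA(ns) && length(unique(as.vector(ns))) == 1L) ns <- ns[1, 1]
  grm_matrix(v, ids, n_snps = ns)
}
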