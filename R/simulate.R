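#' Configuration for synthetic cohort simulation
#'
#' Collects the parameters of the generative model used to validate the
#' GxE heritability pipeline: cohort and marker panel size, the allele
#' frequency spectrum, environment composition, and the target variance
#' decomposition. Phenotypes are generated under the same mixed linear model
#' the estimator fits, \eqn{y = X\beta + g + ge + \epsilon}, so REML applied
#' to simulated data is a direct parameter-recovery check.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_snps Number of biallelic autosomal SNPs (>= 1).
#' @param maf_low,maf_high Bounds of the uniform allele-frequency spectrum,
#'   in (0, 0.5] with \code{maf_low <= maf_high}.
#' @param env_proportions Fractions of the cohort per environment level;
#'   must sum to 1. Default 40/60, echoing an unequal rural/urban split.
#' @param h2_g Target proportion of phenotypic variance from additive
#'   genetic effects, \eqn{\sigma_g^2/\sigma_p^2}, in [0, 1].
#' @param h2_ge Target proportion from genotype-environment interaction,
#'   \eqn{\sigma_{ge}^2/\sigma_p^2}; \code{h2_g + h2_ge} must be <= 1.
#' @param rg Cross-environment genetic correlation in [-1, 1], used by
#'   \code{\link{simulate_bivariate}}.
#' @param h2_bivar Optional length-2 vector of per-environment genetic
#'   variance proportions for the bivariate generator; defaults to
#'   \code{c(h2_g, h2_g)}.
#' @param fixed_effects Optional named numeric vector of fixed-effect
#'   coefficients applied to environment indicator columns (see
#'   \code{\link{simulate_phenotype}}). Default none.
#' @param missing_rate Per-genotype missingness probability in [0, 1).
#' @param seed Integer root seed; child streams for genotypes, covariates and
#'   phenotypes are derived from it by fixed offsets.
#'
#' @return An object of class \code{"sim_config"}.
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_snps = 100, h2_g = 0.2,
#'                   h2_ge = 0.1, seed = 1)
#' cfg
#' @export
sim_config <- function(n_individuals, n_snps, maf_low = 0.05, maf_high = 0.5,
                       env_proportions = c(0.4, 0.6), h2_g = 0, h2_ge = 0,
                       rg = 1, h2_bivar = NULL, fixed_effects = NULL,
                       missing_rate = 0, seed = 1L) {
  if (!is_count(n_individuals) || n_individuals < 2)
    stopf("`n_individuals` must be an integer >= 2")
  if (!is_count(n_snps) || n_snps < 1)
    stopf("`n_snps` must be an integer >= 1")
  if (!is.numeric(maf_low) || !is.numeric(maf_high) ||
      maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high)
    stopf("allele-frequency bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  if (!is.numeric(env_proportions) || length(env_proportions) < 1 ||
      any(env_proportions < 0) ||
      abs(sum(env_proportions) - 1) > 1e-12)
    stopf("`env_proportions` must be nonnegative and sum to 1 (within 1e-12)")
  if (!is_prob(h2_g) || !is_prob(h2_ge))
    stopf("`h2_g` and `h2_ge` must lie in [0, 1]")
  if (h2_g + h2_ge > 1)
    stopf("h2_g + h2_ge must be <= 1 (got %.3f)", h2_g + h2_ge)
  if (!is.numeric(rg) || length(rg) != 1L || is.na(rg) || abs(rg) > 1)
    stopf("`rg` must lie in [-1, 1]")
  if (is.null(h2_bivar)) h2_bivar <- c(h2_g, h2_g)
  if (length(h2_bivar) != 2L || any(h2_bivar < 0) || any(h2_bivar > 1))
    stopf("`h2_bivar` must be two proportions in [0, 1]")
  if (!is.null(fixed_effects) && !is.numeric(fixed_effects))
    stopf("`fixed_effects` must be a numeric vector")
  if (!is_prob(missing_rate) || missing_rate >= 1)
    stopf("`missing_rate` must lie in [0, 1)")
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_low = maf_low, maf_high = maf_high,
    env_proportions = env_proportions, h2_g = h2_g, h2_ge = h2_ge,
    rg = rg, h2_bivar = h2_bivar, fixed_effects = fixed_effects,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d   SNPs: %d   MAF ~ U(%.3g, %.3g)\n",
              x$n_individuals, x$n_snps, x$maf_low, x$maf_high))
  cat(sprintf("  environments: %s\n",
              paste(sprintf("%.0f%%", 100 * x$env_proportions),
                    collapse = " / ")))
  cat(sprintf("  h2_g = %.3f   h2_ge = %.3f   rg = %.2f   seed = %d\n",
              x$h2_g, x$h2_ge, x$rg, x$seed))
  invisible(x)
}

#' Simulate a biallelic genotype matrix
#'
#' Draws per-SNP reference-allele frequencies uniformly on
#' \code{[maf_low, maf_high]} and genotype dosages as the sum of two
#' independent Bernoulli draws (Hardy-Weinberg sampling, no linkage
#' disequilibrium). Output is deterministic given \code{cfg$seed}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A \code{\link{genotype_matrix}}; the true simulation frequencies
#'   are attached as attribute \code{"true_freq"}.
#' @examples
#' G <- simulate_genotypes(sim_config(50, 20, seed = 7))
#' dim(G$dosage)
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_individuals
  m <- cfg$n_snps
  with_seed(child_seed(cfg$seed, "genotypes"), {
    p <- runif(m, cfg$maf_low, cfg$maf_high)
    d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    if (cfg$missing_rate > 0) {
      miss <- runif(n * m) < cfg$missing_rate
      d[miss] <- NA_integer_
    }
    snps <- data.frame(
      id = sprintf("snp%04d", seq_len(m)),
      chr = ((seq_len(m) - 1L) %% 22L) + 1L,
      pos = seq_len(m) * 1000L,
      a1 = "A", a2 = "B",
      stringsAsFactors = FALSE
    )
    G <- genotype_matrix(d, snps = snps,
                         sample_ids = sprintf("id%05d", seq_len(n)))
    attr(G, "true_freq") <- p
    G
  })
}

#' Simulate the sample table of a two-area cohort
#'
#' Generates per-individual covariates for a cohort recruited from two
#' geographical areas: sex (A/B, balanced), area (1/2 with the configured
#' proportions), and birth year uniform on 1931-1963, spanning three
#' birth-year bands.
#'
#' @param cfg A \code{\link{sim_config}} whose \code{env_proportions} give the
#'   area split (first level = area 1).
#' @return A data frame with columns \code{IID}, \code{SEX}, \code{AREA},
#'   \code{BIRTH_YEAR}.
#' @export
simulate_samples <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_individuals
  with_seed(child_seed(cfg$seed, "samples"), {
    props <- cfg$env_proportions
    counts <- floor(props * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(props * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    area <- sample(rep(seq_along(props), counts))
    data.frame(
      IID = sprintf("id%05d", seq_len(n)),
      SEX = sample(c("A", "B"), n, replace = TRUE),
      AREA = area,
      BIRTH_YEAR = sample(1931:1963, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# Column-standardize dosages using per-SNP allele frequencies p (true
# frequencies when available). Missing entries become 0 (mean imputation on
# the standardized scale).
standardize_dosage <- function(d, p) {
  z <- sweep(d, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  z
}

#' Simulate phenotypes under the additive + GxE variance decomposition
#'
#' Generates a quantitative phenotype whose variance decomposes into additive
#' genetic, genotype-environment interaction, and residual parts at the
#' configured proportions. Per-SNP shared effects are
#' \eqn{u_i \sim N(0, h^2_g/m)} and, independently for each environment level
#' \eqn{e}, interaction deviations \eqn{v_i(e) \sim N(0, h^2_{ge}/m)}; the
#' phenotype of individual \eqn{j} in environment \eqn{e_j} is
#' \deqn{y_j = \sum_i z_{ij} u_i + \sum_i z_{ij} v_i(e_j) + x_j'\beta +
#'       \epsilon_j,}
#' with \eqn{z} the dosages standardized by the true allele frequencies and
#' \eqn{\epsilon_j \sim N(0, 1 - h^2_g - h^2_{ge})}. Drawing interaction
#' deviations independently per environment makes
#' \eqn{cov(ge_j, ge_k) = A_{jk}\sigma^2_{ge}} for same-environment pairs and
#' 0 across environments - exactly the masked-GRM covariance the estimator
#' assumes.
#'
#' @param G A \code{\link{genotype_matrix}} (typically from
#'   \code{\link{simulate_genotypes}}).
#' @param env A factor of environment levels, one per individual (see
#'   \code{\link{encode_env}}).
#' @param cfg A \code{\link{sim_config}}; \code{fixed_effects}, if given, are
#'   coefficients for the non-reference environment indicator columns.
#' @return A list with components \code{y} (named phenotype vector) and
#'   \code{truth}, a record of the drawn effect vectors (\code{u}, \code{v}),
#'   the realized component vectors (\code{g}, \code{ge}, \code{eps}) and
#'   their realized variance fractions, and the seed used.
#' @examples
#' cfg <- sim_config(300, 200, h2_g = 0.3, h2_ge = 0.2, seed = 2)
#' G <- simulate_genotypes(cfg)
#' env <- factor(rep(c(1, 2), length.out = 300))
#' sim <- simulate_phenotype(G, env, cfg)
#' sim$truth$realized
#' @export
simulate_phenotype <- function(G, env, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  env <- as.factor(env)
  n <- nrow(G$dosage)
  m <- ncol(G$dosage)
  if (length(env) != n) stopf("`env` must assign a level to every individual")
  if (anyNA(env)) stopf("`env` must assign a level to every individual")
  if (cfg$h2_g + cfg$h2_ge > 1) stopf("h2_g + h2_ge must be <= 1")
  p <- attr(G, "true_freq")
  if (is.null(p)) p <- colMeans(G$dosage, na.rm = TRUE) / 2
  z <- standardize_dosage(G$dosage, p)
  lev <- levels(env)
  with_seed(child_seed(cfg$seed, "phenotype"), {
    u <- rnorm(m, 0, sqrt(cfg$h2_g / m))
    v <- matrix(rnorm(m * length(lev), 0, sqrt(cfg$h2_ge / m)),
                nrow = m, ncol = length(lev), dimnames = list(NULL, lev))
    g <- drop(z %*% u)
    ge <- rowSums(z * t(v[, as.integer(env), drop = FALSE]))
    eps <- rnorm(n, 0, sqrt(1 - cfg$h2_g - cfg$h2_ge))
    xb <- numeric(n)
    if (!is.null(cfg$fixed_effects) && length(cfg$fixed_effects) > 0) {
      X <- stats::model.matrix(~env)[, -1, drop = FALSE]
      b <- rep_len(cfg$fixed_effects, ncol(X))
      xb <- drop(X %*% b)
    }
    y <- g + ge + xb + eps
    names(y) <- G$sample_ids
    vy <- var(y)
    truth <- structure(list(
      u = u, v = v, g = g, ge = ge, eps = eps, env = env,
      realized = c(h2_g = var(g) / vy, h2_ge = var(ge) / vy,
                   resid = var(eps) / vy),
      seed = cfg$seed
    ), class = "truth_record")
    list(y = y, truth = truth)
  })
}

#' Simulate two environments as genetically correlated traits
#'
#' The bivariate analogue of \code{\link{simulate_phenotype}}: each SNP gets a
#' pair of effects \eqn{(u_i^{(1)}, u_i^{(2)})} from a bivariate normal with
#' correlation \code{cfg$rg} and per-environment variances
#' \code{cfg$h2_bivar / m}; an individual's phenotype uses the effect vector
#' of its own environment. Because each individual is observed in exactly one
#' environment, the two phenotype sets behave as two traits measured on
#' disjoint samples, the setting of \code{\link{bivar_reml}}.
#'
#' @inheritParams simulate_phenotype
#' @param env A factor with exactly two levels.
#' @return As \code{\link{simulate_phenotype}}; \code{truth$u} is an m x 2
#'   matrix of per-environment effects.
#' @export
simulate_bivariate <- function(G, env, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  env <- as.factor(env)
  if (nlevels(env) != 2L) stopf("bivariate simulation needs exactly two environment levels")
  if (abs(cfg$rg) > 1) stopf("`rg` must lie in [-1, 1]")
  n <- nrow(G$dosage)
  m <- ncol(G$dosage)
  if (length(env) != n || anyNA(env))
    stopf("`env` must assign a level to every individual")
  p <- attr(G, "true_freq")
  if (is.null(p)) p <- colMeans(G$dosage, na.rm = TRUE) / 2
  z <- standardize_dosage(G$dosage, p)
  h2 <- cfg$h2_bivar
  rg <- cfg$rg
  with_seed(child_seed(cfg$seed, "bivariate"), {
    z1 <- rnorm(m)
    z2 <- rnorm(m)
    u1 <- sqrt(h2[1] / m) * z1
    u2 <- sqrt(h2[2] / m) * (rg * z1 + sqrt(1 - rg^2) * z2)
    u <- cbind(u1, u2)
    colnames(u) <- levels(env)
    idx <- as.integer(env)
    g <- rowSums(z * t(u[, idx, drop = FALSE]))
    eps <- rnorm(n, 0, sqrt(1 - h2[idx]))
    y <- g + eps
    names(y) <- G$sample_ids
    truth <- structure(list(
      u = u, g = g, eps = eps, env = env, rg = rg, h2 = h2, seed = cfg$seed
    ), class = "truth_record")
    list(y = y, truth = truth)
  })
}

#' Inject related pairs into a genotype matrix
#'
#' Rebuilds the second member of each designated pair by copying each of the
#' first member's two alleles with probability \code{copy_fraction} and
#' redrawing from the population frequency otherwise. Under the realized-GRM
#' estimator the expected relationship of a spiked pair equals
#' \code{copy_fraction}, so this provides calibrated material for testing the
#' relatedness-pruning rule.
#'
#' @param G A \code{\link{genotype_matrix}}.
#' @param n_pairs Number of pairs to spike; pairs are (1,2), (3,4), ...
#' @param copy_fraction Probability in [0, 1] of copying an allele.
#' @param seed Integer seed for the resampling stream.
#' @return The modified \code{genotype_matrix}, with the spiked pairs recorded
#'   in attribute \code{"spiked_pairs"} (a 2-column index matrix).
#' @export
spike_relatives <- function(G, n_pairs, copy_fraction, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosage)
  if (!is_count(n_pairs) || n_pairs > n %/% 2)
    stopf("`n_pairs` must be an integer <= n/2")
  if (!is_prob(copy_fraction))
    stopf("`copy_fraction` must lie in [0, 1]")
  p <- attr(G, "true_freq")
  if (is.null(p)) p <- colMeans(G$dosage, na.rm = TRUE) / 2
  m <- ncol(G$dosage)
  pairs <- cbind(first = 2L * seq_len(n_pairs) - 1L,
                 second = 2L * seq_len(n_pairs))
  with_seed(child_seed(seed, "spike"), {
    for (k in seq_len(n_pairs)) {
      src <- G$dosage[pairs[k, 1L], ]
      # split the source dosage into two exchangeable allele indicators
      # (heterozygote order randomized so each allele is Bernoulli(p))
      a1 <- as.integer(src >= 1)
      a2 <- as.integer(src == 2)
      het <- which(!is.na(src) & src == 1L)
      flip <- het[runif(length(het)) < 0.5]
      a1[flip] <- 0L
      a2[flip] <- 1L
      keep1 <- runif(m) < copy_fraction
      keep2 <- runif(m) < copy_fraction
      b1 <- ifelse(keep1, a1, rbinom(m, 1L, p))
      b2 <- ifelse(keep2, a2, rbinom(m, 1L, p))
      new <- b1 + b2
      new[is.na(src)] <- NA_integer_
      G$dosage[pairs[k, 2L], ] <- new
    }
  })
  attr(G, "spiked_pairs") <- pairs
  G
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running \code{\link{simulate_genotypes}},
#' \code{\link{simulate_samples}} and \code{\link{simulate_phenotype}} (with
#' area as the interacting environment) from one configuration.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param trait Name of the phenotype column to create (default "TRAIT1").
#' @return A list with \code{genotypes}, \code{samples} (sample table with the
#'   phenotype column appended), \code{env} (the area factor), and
#'   \code{truth}.
#' @export
simulate_cohort <- function(cfg, trait = "TRAIT1") {
  G <- simulate_genotypes(cfg)
  samples <- simulate_samples(cfg)
  env <- factor(samples$AREA)
  names(env) <- samples$IID
  attr(env, "env_name") <- "area"
  sim <- simulate_phenotype(G, env, cfg)
  samples[[trait]] <- as.numeric(sim$y)
  list(genotypes = G, samples = samples, env = env, truth = sim$truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Simulation truth record (seed", x$seed, ")\n")
  if (!is.null(x$realized)) {
    cat(sprintf("  realized variance fractions: g = %.3f, ge = %.3f, resid = %.3f\n",
                x$realized[1], x$realized[2], x$realized[3]))
  }
  if (!is.null(x$rg)) cat(sprintf("  bivariate rg = %.2f\n", x$rg))
  invisible(x)
}
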