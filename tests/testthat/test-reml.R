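# AI-REML estimator: grid-search likelihood oracle, boundary LRT mapping,
# parameter recovery, and degenerate-model behaviour.

make_small_instance <- function(n, m, h2_g, h2_ge = 0, seed = 1) {
  cfg <- sim_config(n, m, h2_g = h2_g, h2_ge = h2_ge, seed = seed)
  G <- simulate_genotypes(cfg)
  env <- factor(rep(1:2, length.out = n))
  names(env) <- G$sample_ids
  sim <- simulate_phenotype(G, env, cfg)
  list(G = G, env = env, y = sim$y, A = compute_grm(G))
}

test_that("AI-REML matches a dense grid search of the likelihood (n <= 25)", {
  # two components: additive + residual
  cfg <- sim_config(20, 30, h2_g = 0.5, seed = 51)
  G <- simulate_genotypes(cfg)
  env <- factor(rep(1:2, 10))
  names(env) <- G$sample_ids
  y <- simulate_phenotype(G, env, cfg)$y
  A <- compute_grm(G)
  fit <- greml(y, list(G = A))
  X <- matrix(1, 20, 1)
  grid <- oracle_grid_reml(unname(y), X, list(A$values), step = 0.005)
  expect_lt(abs(fit$props[["V(G)/Vp"]] - grid$props[1]), 0.01)

  # three components: additive + interaction + residual
  cfg3 <- sim_config(25, 40, h2_g = 0.3, h2_ge = 0.4, seed = 52)
  G3 <- simulate_genotypes(cfg3)
  env3 <- factor(rep(1:2, length.out = 25))
  names(env3) <- G3$sample_ids
  y3 <- simulate_phenotype(G3, env3, cfg3)$y
  A3 <- compute_grm(G3)
  M3 <- gxe_grm(A3, env3)
  fit3 <- greml(y3, list(G = A3, GxE = M3))
  X3 <- matrix(1, 25, 1)
  grid3 <- oracle_grid_reml(unname(y3), X3, list(A3$values, M3$values),
                            step = 0.005)
  expect_lt(abs(fit3$props[["V(G)/Vp"]] - grid3$props[1]), 0.01)
  expect_lt(abs(fit3$props[["V(GxE)/Vp"]] - grid3$props[2]), 0.01)
  # and the reported likelihood is not beaten by the grid
  expect_gte(fit3$logLik, grid3$logLik - 0.01)
})

test_that("identity genetic structure is flagged as unidentifiable", {
  set.seed(53)
  n <- 40
  A <- grm_matrix(diag(n), paste0("s", 1:n))
  y <- setNames(rnorm(n), paste0("s", 1:n))
  fit <- greml(y, list(G = A))
  expect_false(fit$converged)
  expect_true("flat_likelihood" %in% fit$flags)
})

test_that("boundary LRT maps statistics to mixture p-values", {
  t1 <- lrt(5.84, 0)
  expect_equal(t1$statistic, 11.68)
  expect_equal(signif(t1$p_value, 2), 3.2e-4)
  t2 <- lrt(2.19, 0)
  expect_equal(t2$statistic, 4.38)
  expect_equal(signif(t2$p_value, 2), 1.8e-2)
  t0 <- lrt(7.5, 7.5)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 0.5)
  expect_warning(tn <- lrt(1, 1.2), "clamped")
  expect_equal(tn$statistic, 0)
})

test_that("lrt on fits demands nesting and full >= reduced likelihood", {
  inst <- make_small_instance(60, 60, h2_g = 0.3, h2_ge = 0.3, seed = 54)
  M <- gxe_grm(inst$A, inst$env)
  full <- greml(inst$y, list(G = inst$A, GxE = M))
  reduced <- greml(inst$y, list(G = inst$A))
  expect_gte(full$logLik, reduced$logLik - 1e-6)
  res <- lrt(full, reduced)
  expect_gte(res$statistic, 0)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_error(lrt(reduced, full), "fewer component")
  other <- greml(inst$y, list(H = M))
  expect_error(lrt(full, other), "not nested")
})

test_that("variance proportions are valid and SEs finite on typical fits", {
  inst <- make_small_instance(150, 150, h2_g = 0.4, h2_ge = 0.2, seed = 55)
  M <- gxe_grm(inst$A, inst$env)
  fit <- greml(inst$y, list(G = inst$A, GxE = M))
  expect_true(all(fit$props >= 0 & fit$props <= 1))
  expect_lte(sum(fit$props), 1)
  expect_true(all(is.finite(fit$se_props)))
  expect_true(all(fit$components >= 0))
  expect_true(is.finite(fit$logLik))
  # methods behave
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(dim(vcov(fit, "varcomp")), c(3, 3))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n, 2))
})

test_that("REML recovers the simulation grid without systematic bias", {
  cells <- list(c(0, 0.27), c(0.27, 0), c(0.1, 0.15))
  for (cell in cells) {
    cfg <- sim_config(800, 800, h2_g = cell[1], h2_ge = cell[2],
                      seed = 60 + round(100 * cell[1]))
    G <- simulate_genotypes(cfg)
    env <- factor(rep(1:2, length.out = 800))
    names(env) <- G$sample_ids
    A <- compute_grm(G)
    M <- gxe_grm(A, env)
    est <- matrix(NA_real_, 8, 2)
    for (r in 1:8) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r
      y <- simulate_phenotype(G, env, cfg_r)$y
      fit <- greml(y, list(G = A, GxE = M))
      est[r, ] <- c(fit$props[["V(G)/Vp"]], fit$props[["V(GxE)/Vp"]])
    }
    expect_lt(abs(mean(est[, 1]) - cell[1]), 0.05)
    expect_lt(abs(mean(est[, 2]) - cell[2]), 0.05)
  }
})

test_that("GxE LRT holds its size under the no-interaction null", {
  n <- 250
  m <- 250
  cfg0 <- sim_config(n, m, h2_g = 0.2, h2_ge = 0, seed = 70)
  G <- simulate_genotypes(cfg0)
  env <- factor(rep(1:2, length.out = n))
  names(env) <- G$sample_ids
  A <- compute_grm(G)
  M <- gxe_grm(A, env)
  Xe <- cbind(env2 = as.numeric(env == "2"))
  rownames(Xe) <- G$sample_ids
  reject <- logical(100)
  for (r in 1:100) {
    cfg_r <- cfg0
    cfg_r$seed <- 70 + r
    y <- simulate_phenotype(G, env, cfg_r)$y
    full <- greml(y, list(G = A, GxE = M), X = Xe)
    reduced <- greml(y, list(G = A), X = Xe)
    reject[r] <- lrt(full, reduced)$p_value < 0.05
  }
  # mixture null is conservative-to-exact: rate <= 0.05 + 2 binomial SDs
  expect_lte(mean(reject), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("a singular fixed-effects design is rejected", {
  inst <- make_small_instance(50, 40, h2_g = 0.3, seed = 71)
  X <- cbind(a = rep(1, 50), b = rep(1, 50))
  rownames(X) <- names(inst$y)
  expect_error(greml(inst$y, list(G = inst$A), X = X), "singular")
})
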