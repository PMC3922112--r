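# Synthetic-data generator: determinism, frequency calibration, and the
# variance decomposition the phenotype model promises.

test_that("genotype support, determinism and frequency calibration", {
  cfg <- sim_config(4, 1, maf_low = 0.5, maf_high = 0.5, seed = 42)
  G <- simulate_genotypes(cfg)
  expect_true(all(G$dosage %in% 0:2))
  expect_identical(simulate_genotypes(cfg)$dosage, G$dosage)

  cfg2 <- sim_config(20000, 5, maf_low = 0.3, maf_high = 0.3, seed = 7)
  G2 <- simulate_genotypes(cfg2)
  freq <- colMeans(G2$dosage) / 2
  expect_true(all(abs(freq - 0.3) < 0.01))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(100, 10, h2_g = 0.6, h2_ge = 0.5), "<= 1")
  expect_error(sim_config(100, 10, maf_low = 0.4, maf_high = 0.2), "maf")
  expect_error(sim_config(100, 10, env_proportions = c(0.5, 0.6)), "sum to 1")
  expect_error(sim_config(1, 10), "n_individuals")
  expect_error(sim_config(100, 10, rg = 1.5), "rg")
})

test_that("null model gives unit phenotype variance and no structure", {
  cfg <- sim_config(2000, 50, h2_g = 0, h2_ge = 0, seed = 11)
  G <- simulate_genotypes(cfg)
  env <- factor(rep(1:2, length.out = 2000))
  sim <- simulate_phenotype(G, env, cfg)
  expect_gt(var(sim$y), 0.9)
  expect_lt(var(sim$y), 1.1)
  expect_true(all(sim$truth$u == 0))
})

test_that("realized variance components add up to the phenotype variance", {
  cfg <- sim_config(2000, 300, h2_g = 0.3, h2_ge = 0.2, seed = 13)
  G <- simulate_genotypes(cfg)
  env <- factor(rep(1:2, length.out = 2000))
  sim <- simulate_phenotype(G, env, cfg)
  tr <- sim$truth
  comp_var <- var(tr$g) + var(tr$ge) + var(tr$eps)
  expect_lt(abs(comp_var - var(sim$y)) / var(sim$y), 0.05)
  # variance budget near 1 and realized fractions near targets
  expect_gt(var(sim$y), 0.9)
  expect_lt(var(sim$y), 1.1)
  expect_lt(abs(tr$realized[["h2_g"]] - 0.3), 0.1)
  expect_lt(abs(tr$realized[["h2_ge"]] - 0.2), 0.1)
})

test_that("interaction effects covary through the GRM within environments only", {
  cfg <- sim_config(300, 500, h2_g = 0, h2_ge = 0.5, seed = 17)
  G <- simulate_genotypes(cfg)
  env <- factor(rep(1:2, each = 150))
  sim <- simulate_phenotype(G, env, cfg)
  ge <- sim$truth$ge
  p <- attr(G, "true_freq")
  z <- sweep(sweep(G$dosage, 2, 2 * p, "-"), 2,
             sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(z) / ncol(z)
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  prod_ge <- ge[pairs[, 1]] * ge[pairs[, 2]]
  a_jk <- A[pairs]
  same <- env[pairs[, 1]] == env[pairs[, 2]]
  slope_same <- coef(lm(prod_ge[same] ~ a_jk[same]))[2]
  slope_diff <- coef(lm(prod_ge[!same] ~ a_jk[!same]))[2]
  # tolerances set to ~3 Monte-Carlo SDs of the regression slopes
  expect_lt(abs(slope_same - 0.5), 0.25)
  expect_lt(abs(slope_diff), 0.25)
})

test_that("bivariate generator respects the target genetic correlation", {
  cfg1 <- sim_config(100, 400, h2_g = 0.4, rg = 1, seed = 19)
  G <- simulate_genotypes(cfg1)
  env <- factor(rep(1:2, each = 50))
  s1 <- simulate_bivariate(G, env, cfg1)
  expect_equal(s1$truth$u[, 1], s1$truth$u[, 2])

  cfg0 <- sim_config(100, 400, h2_g = 0.4, rg = 0, seed = 19)
  s0 <- simulate_bivariate(G, env, cfg0)
  expect_lt(abs(cor(s0$truth$u[, 1], s0$truth$u[, 2])), 0.15)

  cfgn <- sim_config(100, 400, h2_g = 0.4, rg = -0.26, seed = 19)
  sn <- simulate_bivariate(G, env, cfgn)
  expect_lt(abs(cor(sn$truth$u[, 1], sn$truth$u[, 2]) + 0.26), 0.15)

  expect_identical(simulate_bivariate(G, env, cfg1)$y, s1$y)
  expect_error(simulate_bivariate(G, factor(rep(1, 100)), cfg1), "two")
})

test_that("spiked relative pairs hit the intended GRM relationship", {
  # n large enough that sample-frequency centering bias (~1/n) is negligible
  cfg <- sim_config(100, 5000, seed = 23)
  G <- simulate_genotypes(cfg)

  G1 <- spike_relatives(G, n_pairs = 1, copy_fraction = 1, seed = 1)
  expect_identical(G1$dosage[1, ], G1$dosage[2, ])
  A1 <- suppressWarnings(compute_grm(G1))
  expect_lt(abs(A1$values[1, 2] - A1$values[1, 1]), 0.05)

  G5 <- spike_relatives(G, n_pairs = 2, copy_fraction = 0.5, seed = 1)
  A5 <- suppressWarnings(compute_grm(G5))
  expect_lt(abs(A5$values[1, 2] - 0.5), 0.05)
  expect_lt(abs(A5$values[3, 4] - 0.5), 0.05)

  G0 <- spike_relatives(G, n_pairs = 1, copy_fraction = 0, seed = 1)
  A0 <- suppressWarnings(compute_grm(G0))
  expect_lt(abs(A0$values[1, 2]), 0.1)

  expect_error(spike_relatives(G, 60, 0.5), "n/2")
  expect_error(spike_relatives(G, 1, 1.5), "copy_fraction")
})

test_that("environment assignment follows the configured proportions", {
  cfg <- sim_config(1000, 10, env_proportions = c(0.4, 0.6), seed = 29)
  s <- simulate_samples(cfg)
  expect_equal(sum(s$AREA == 1), 400)
  expect_equal(sum(s$AREA == 2), 600)
  expect_true(all(s$BIRTH_YEAR >= 1931 & s$BIRTH_YEAR <= 1963))
  expect_identical(simulate_samples(cfg), s)
})
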