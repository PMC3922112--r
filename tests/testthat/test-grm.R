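# GRM estimator, relatedness pruning, environment masking, and the GCTA
# text-format round trip.

test_that("GRM entries match hand evaluation of the estimator", {
  # one SNP with sample frequency 0.5
  d <- matrix(c(2L, 0L, 1L, 1L), ncol = 1)
  A <- compute_grm(genotype_matrix(d))
  expect_equal(A$values[1, 2], -2)        # (2-1)(0-1)/(2*0.5*0.5)
  expect_equal(A$values[3, 4], 0)         # centered dosage zero
  expect_equal(A$values[1, 1], 2)         # same formula on the diagonal
  expect_equal(A$values[1, 2], oracle_grm_entry(d, 1, 2))

  set.seed(21)
  d2 <- matrix(rbinom(8 * 20, 2, 0.35), nrow = 8)
  A2 <- compute_grm(genotype_matrix(d2))
  for (pair in list(c(1, 2), c(3, 7), c(5, 5))) {
    expect_equal(A2$values[pair[1], pair[2]],
                 oracle_grm_entry(d2, pair[1], pair[2]), tolerance = 1e-12)
  }
})

test_that("missing genotypes are handled by per-pair SNP counts", {
  set.seed(22)
  d <- matrix(rbinom(6 * 30, 2, 0.4), nrow = 6)
  d[1, 1:10] <- NA
  d[2, 5:15] <- NA
  A <- compute_grm(genotype_matrix(d))
  expect_equal(A$values[1, 2], oracle_grm_entry(d, 1, 2), tolerance = 1e-12)
  expect_equal(A$n_snps[1, 2], sum(!is.na(d[1, ]) & !is.na(d[2, ])))
})

test_that("GRM is calibrated on unrelated HWE data", {
  cfg <- sim_config(500, 5000, maf_low = 0.1, seed = 33)
  A <- compute_grm(simulate_genotypes(cfg))
  expect_lt(abs(mean(diag(A$values)) - 1), 0.02)
  off <- A$values[upper.tri(A$values)]
  # sample-frequency centering forces sum_k A_jk = 0, so the off-diagonal
  # mean sits at -tr(A)/(n(n-1)) ~ -1/(n-1) rather than exactly 0
  centre <- -sum(diag(A$values)) / (500 * 499)
  expect_lt(abs(mean(off) - centre), 3 / sqrt(length(off) * 5000))
  expect_lt(max(abs(A$values - t(A$values))), 1e-12)
})

test_that("GRM is invariant to SNP order and equivariant to sample order", {
  set.seed(23)
  d <- matrix(rbinom(10 * 50, 2, 0.3), nrow = 10)
  G <- genotype_matrix(d)
  A <- compute_grm(G)
  sperm <- sample(10)
  cperm <- sample(50)
  G2 <- genotype_matrix(d[sperm, cperm],
                        sample_ids = G$sample_ids[sperm])
  A2 <- compute_grm(G2)
  expect_equal(unname(A2$values), unname(A$values[sperm, sperm]),
               tolerance = 1e-12)
})

test_that("monomorphic SNPs are excluded, empty panels rejected", {
  d <- cbind(mono = rep(2L, 5), poly = c(0L, 1L, 2L, 1L, 0L))
  expect_warning(A <- compute_grm(genotype_matrix(d)), "monomorphic")
  expect_error(compute_grm(genotype_matrix(matrix(rep(2L, 10), ncol = 2))),
               "polymorphic")
})

test_that("pruning drops hubs first and leaves no above-cutoff pair", {
  ids <- paste0("s", 1:2)
  v <- matrix(c(1, 0.03, 0.03, 1), 2, dimnames = list(ids, ids))
  expect_warning(keep <- prune_related(grm_matrix(v, ids), cutoff = 0.025),
                 "fewer than 2")
  expect_identical(keep, "s1")   # ties keep the earlier individual
})

test_that("triangle case keeps the pair and matches the exhaustive optimum", {
  ids <- paste0("s", 1:3)
  v <- diag(3)
  v[1, 2] <- v[2, 1] <- 0.05
  v[1, 3] <- v[3, 1] <- 0.05
  v[2, 3] <- v[3, 2] <- 0.01
  A <- grm_matrix(v, ids)
  keep <- prune_related(A, cutoff = 0.025)
  expect_identical(keep, c("s2", "s3"))
  expect_equal(length(keep), length(oracle_max_unrelated(v, 0.025)))

  # all pairs below the cutoff: no-op
  expect_identical(prune_related(A, cutoff = 0.1), ids)
})

test_that("pruned sets never contain an above-cutoff pair (random GRMs)", {
  set.seed(24)
  for (rep in 1:5) {
    n <- 12
    v <- matrix(rnorm(n * n, 0, 0.03), n)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    ids <- paste0("x", 1:n)
    A <- grm_matrix(v, ids)
    keep <- prune_related(A, cutoff = 0.025)
    sub <- v[match(keep, ids), match(keep, ids)]
    diag(sub) <- 0
    expect_true(all(sub <= 0.025))
    expect_gte(length(keep), length(oracle_max_unrelated(v, 0.025)) - 2)
  }
})

test_that("environment masking zeroes exactly the cross-environment pairs", {
  set.seed(25)
  G <- simulate_genotypes(sim_config(20, 100, seed = 25))
  A <- compute_grm(G)
  env <- factor(rep(c("u", "r"), 10))
  names(env) <- A$sample_ids
  M <- gxe_grm(A, env)
  same <- outer(env, env, "==")
  expect_equal(M$values[same], A$values[same])
  expect_true(all(M$values[!same] == 0))
  # idempotent; complementary mask annihilates it
  expect_equal(gxe_grm(M, env)$values, M$values)
  expect_true(all((M$values * !same) == 0))
  # single environment: mask is a no-op
  one <- factor(rep("a", 20))
  names(one) <- A$sample_ids
  expect_equal(gxe_grm(A, one)$values, A$values)
  # permutation commutes with masking
  perm <- sample(20)
  Ap <- grm_matrix(A$values[perm, perm], A$sample_ids[perm])
  Mp <- gxe_grm(Ap, env[perm])
  expect_equal(unname(Mp$values), unname(M$values[perm, perm]))
  # missing environment errors
  expect_error(gxe_grm(A, env[1:10]), "missing")
})

test_that("GCTA text format round trips", {
  G <- simulate_genotypes(sim_config(15, 80, missing_rate = 0.05, seed = 26))
  A <- compute_grm(G)
  prefix <- file.path(tempdir(), "grmtest")
  write_grm(A, prefix)
  B <- read_grm(prefix)
  expect_equal(B$values, A$values, tolerance = 1e-8)
  expect_identical(B$sample_ids, A$sample_ids)
  expect_equal(B$n_snps, A$n_snps)
})
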