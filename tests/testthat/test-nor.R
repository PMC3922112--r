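# Genotype groups from GRM hubs and norm-of-reaction summaries.

toy_grm <- function(extra_link = FALSE) {
  n <- 8
  v <- diag(n)
  link <- function(i, j, val = 0.05) {
    v[i, j] <<- val
    v[j, i] <<- val
  }
  link(1, 2); link(1, 3); link(1, 4)   # hub 1 with three partners
  link(5, 6); link(5, 7)               # hub 5 with two partners
  if (extra_link) link(4, 5)
  grm_matrix(v, paste0("s", 1:n))
}

test_that("hubs are ranked by partner count and groups collected", {
  A <- toy_grm()
  grp <- build_genotype_groups(A, threshold = 0.02, k = 2)
  expect_equal(grp[[1]]$hub, "s1")
  expect_equal(grp[[1]]$members, paste0("s", 1:4))
  expect_equal(grp[[2]]$hub, "s5")
  expect_equal(grp[[2]]$members, paste0("s", 5:7))
  # brute-force partner counts confirm the hub ranking
  counts <- rowSums(A$values > 0.02 & !diag(8))
  expect_equal(order(-counts)[1:2], c(1, 5))
})

test_that("overlapping members are excluded from all groups", {
  A <- toy_grm(extra_link = TRUE)
  grp <- build_genotype_groups(A, threshold = 0.02, k = 2)
  expect_false("s4" %in% grp[[1]]$members)
  expect_false("s4" %in% grp[[2]]$members)
  expect_length(intersect(grp[[1]]$members, grp[[2]]$members), 0)
  before <- attr(grp, "sizes_before_exclusion")
  expect_equal(unname(before), c(4, 4))
})

test_that("groups are pairwise disjoint on random GRMs", {
  set.seed(301)
  for (r in 1:3) {
    n <- 40
    v <- matrix(rnorm(n * n, 0, 0.02), n)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    A <- grm_matrix(v, paste0("x", 1:n))
    grp <- tryCatch(build_genotype_groups(A, threshold = 0.02, k = 3),
                    error = function(e) NULL)
    if (is.null(grp)) next
    mem <- lapply(grp, `[[`, "members")
    for (i in 1:2) for (j in (i + 1):3) {
      expect_length(intersect(mem[[i]], mem[[j]]), 0)
    }
    # determinism
    grp2 <- build_genotype_groups(A, threshold = 0.02, k = 3)
    expect_identical(grp, grp2)
  }
})

test_that("too high a threshold reports how many hubs are possible", {
  A <- toy_grm()
  expect_error(build_genotype_groups(A, threshold = 0.5, k = 2),
               "0 individual")
  expect_error(build_genotype_groups(A, threshold = 0.02, k = 8),
               "cannot form 8")
})

test_that("cell means and standard errors are direct arithmetic", {
  A <- toy_grm()
  grp <- build_genotype_groups(A, threshold = 0.02, k = 2)
  y <- setNames(c(1, 2, 3, 10, 4, 5, 6, 0), paste0("s", 1:8))
  env <- setNames(factor(c("u", "u", "u", "r", "u", "u", "u", "r")),
                  paste0("s", 1:8))
  nor <- reaction_norm_summary(grp, y, env)
  cell <- nor[nor$group == 1 & nor$env == "u", ]
  expect_equal(cell$mean, 2)
  expect_equal(cell$se, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(cell$n, 3)
  # group 2 has nobody in environment r: flagged missing, summary intact
  cell2 <- nor[nor$group == 2 & nor$env == "r", ]
  expect_equal(cell2$n, 0)
  expect_true(is.na(cell2$mean))
  # cell means invariant to reordering of y
  perm <- sample(8)
  nor2 <- reaction_norm_summary(grp, y[perm], env)
  expect_equal(nor$mean, nor2$mean)
})

test_that("parallel profiles give a zero interaction contrast", {
  A <- toy_grm()
  grp <- build_genotype_groups(A, threshold = 0.02, k = 2)
  # construct phenotypes: group effect + common environment effect
  y <- setNames(numeric(8), paste0("s", 1:8))
  env <- setNames(factor(rep(c("u", "r"), 4)), paste0("s", 1:8))
  base <- c(s1 = 0, s2 = 0, s3 = 0, s4 = 0, s5 = 2, s6 = 2, s7 = 2, s8 = 9)
  y <- base + ifelse(env == "u", 1, 0)
  names(y) <- paste0("s", 1:8)
  nor <- reaction_norm_summary(grp, y, env)
  expect_equal(unname(nor_interaction_contrast(nor)), 0)
})

test_that("genetically similar groups show GxE as non-parallel reaction norms", {
  # Three "hub stars": members share ~70% of each hub's alleles, so group
  # members carry correlated interaction effects and the group x area cell
  # means trace non-parallel profiles when h2_ge is large.
  run_once <- function(h2_ge, seed) {
    set.seed(seed)
    m <- 300
    sizes <- c(20, 18, 16)
    p <- runif(m, 0.2, 0.5)
    rows <- list()
    for (s in sizes) {
      hub <- rbinom(m, 2, p)
      rows[[length(rows) + 1L]] <- hub
      a1 <- as.integer(hub >= 1)
      a2 <- as.integer(hub == 2)
      flip <- which(hub == 1L & runif(m) < 0.5)
      a1[flip] <- 0L
      a2[flip] <- 1L
      for (i in seq_len(s - 1)) {
        k1 <- runif(m) < 0.7
        k2 <- runif(m) < 0.7
        rows[[length(rows) + 1L]] <-
          ifelse(k1, a1, rbinom(m, 1, p)) + ifelse(k2, a2, rbinom(m, 1, p))
      }
    }
    # large unrelated background keeps sample-frequency centering from
    # absorbing the stars' shared signal
    for (i in 1:150) rows[[length(rows) + 1L]] <- rbinom(m, 2, p)
    d <- do.call(rbind, rows)
    n <- nrow(d)
    G <- genotype_matrix(d)
    attr(G, "true_freq") <- p
    env <- factor(rep(1:2, length.out = n))
    names(env) <- G$sample_ids
    cfg <- sim_config(n, m, h2_g = 0, h2_ge = h2_ge, seed = seed)
    sim <- simulate_phenotype(G, env, cfg)
    A <- compute_grm(G)
    grp <- build_genotype_groups(A, threshold = 0.53, k = 3)
    nor <- reaction_norm_summary(grp, sim$y, env)
    mean(abs(nor_interaction_contrast(nor)), na.rm = TRUE)
  }
  with_gxe <- vapply(1:12, function(r) run_once(0.85, 400 + r), numeric(1))
  without <- vapply(1:12, function(r) run_once(0, 400 + r), numeric(1))
  expect_gt(mean(with_gxe), mean(without))
})

test_that("locus-specific reaction norms distinguish parallel from crossing", {
  set.seed(302)
  n <- 400
  d <- rbinom(n, 2, 0.5)
  env <- factor(rep(1:2, each = n / 2))
  # no interaction: same slope in both environments
  y_par <- 0.5 * d + ifelse(env == 1, 0.3, -0.3) + rnorm(n, sd = 0.1)
  tab <- snp_reaction_norm(d, y_par, env)
  slopes <- sapply(1:2, function(e) {
    m <- tab$mean[tab$env == levels(env)[e]]
    m[3] - m[1]
  })
  expect_lt(abs(slopes[1] - slopes[2]), 0.15)
  # crossing interaction: +delta in env 1, -delta in env 2
  y_x <- ifelse(env == 1, 0.6, -0.6) * d + rnorm(n, sd = 0.1)
  tab_x <- snp_reaction_norm(d, y_x, env)
  sl_x <- sapply(1:2, function(e) {
    m <- tab_x$mean[tab_x$env == levels(env)[e]]
    m[3] - m[1]
  })
  expect_gt(sl_x[1], 0.5)
  expect_lt(sl_x[2], -0.5)

  expect_warning(one <- snp_reaction_norm(rep(1, n), y_par, env),
                 "monomorphic")
  expect_equal(nrow(one), 2)
  expect_error(snp_reaction_norm(c(3, d[-1]), y_par, env), "dosage")
})
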