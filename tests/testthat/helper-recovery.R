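# Parameter-recovery runners at the reference simulation scale
# (n = 2000 individuals, m = 2000 SNPs): one genotype panel per setting,
# phenotypes redrawn per replicate seed, REML refit from scratch each time.

recovery_univariate <- function(h2_g, h2_ge, split, rep_seeds, panel_seed) {
  n <- 2000L
  cfg0 <- sim_config(n, 2000L, h2_g = h2_g, h2_ge = h2_ge,
                     env_proportions = split, seed = panel_seed)
  G <- simulate_genotypes(cfg0)
  env <- factor(rep(1:2, times = round(split * n)))
  names(env) <- G$sample_ids
  A <- compute_grm(G)
  M <- gxe_grm(A, env)
  Xe <- cbind(env2 = as.numeric(env == "2"))
  rownames(Xe) <- G$sample_ids
  out <- t(vapply(rep_seeds, function(s) {
    cfg <- cfg0
    cfg$seed <- as.integer(s)
    y <- simulate_phenotype(G, env, cfg)$y
    f <- greml(y, list(G = A, GxE = M), X = Xe)
    c(vg = f$props[["V(G)/Vp"]], vge = f$props[["V(GxE)/Vp"]])
  }, numeric(2)))
  colnames(out) <- c("vg", "vge")
  out
}

recovery_bivariate <- function(rg, rep_seeds, panel_seed, h2 = 0.269,
                               split = c(0.4, 0.6)) {
  n <- 2000L
  cfg0 <- sim_config(n, 2000L, h2_g = h2, rg = rg,
                     env_proportions = split, seed = panel_seed)
  G <- simulate_genotypes(cfg0)
  env <- factor(rep(1:2, times = round(split * n)))
  A <- compute_grm(G)
  vapply(rep_seeds, function(s) {
    cfg <- cfg0
    cfg$seed <- as.integer(s)
    sim <- simulate_bivariate(G, env, cfg)
    bivar_reml(sim$y[env == 1], sim$y[env == 2], A)$rg
  }, numeric(1))
}
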