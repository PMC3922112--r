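# End-to-end orchestration: QC -> phenotype adjustment -> GRM -> pruning ->
# per trait x factor GxE REML -> Bonferroni -> follow-up (scan, norms of
# reaction, bivariate) -> additive-estimate comparison.

#' Pipeline run configuration
#'
#' @param traits Character vector of trait column names (>= 1).
#' @param factors Environmental factors to test, a subset of
#'   \code{c("area", "sex", "age_group")} (>= 1).
#' @param bfile PLINK fileset prefix (ignored when \code{simulate} is given).
#' @param sample_file Tab-separated sample table path with columns IID, SEX,
#'   AREA, BIRTH_YEAR and the trait columns.
#' @param simulate Optional \code{\link{sim_config}}; when present the input
#'   cohort is generated rather than read.
#' @param trait_h2 Optional data frame with columns \code{trait},
#'   \code{h2_g}, \code{h2_ge}, \code{factor} giving per-trait simulation
#'   targets; traits not listed are simulated with the \code{simulate}
#'   configuration's values on the \code{area} factor.
#' @param transforms Named character vector of per-trait transforms
#'   ("identity"/"log").
#' @param geno,maf,hwe Marker QC thresholds (missingness, MAF, HWE p).
#' @param prune_cutoff Relatedness cutoff for pruning (default 0.025).
#' @param group_threshold GRM threshold for genotype groups (default 0.020).
#' @param alpha Family-wise significance level (default 0.05).
#' @param followup \code{"significant"} (default; scan/NoR/bivariate only for
#'   family-wise significant trait x factor pairs), \code{"all"}, or
#'   \code{"none"}.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer root seed.
#' @param exam_year Reference year for deriving age from birth year.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(traits, factors = "area", bfile = NULL,
                       sample_file = NULL, simulate = NULL, trait_h2 = NULL,
                       transforms = NULL, geno = 0.05, maf = 0.01,
                       hwe = 1e-6, prune_cutoff = 0.025,
                       group_threshold = 0.020, alpha = 0.05,
                       followup = c("significant", "all", "none"),
                       out_dir = tempfile("gxe_run_"), seed = 1L,
                       exam_year = 2003) {
  if (length(traits) < 1) stopf("at least one trait is required")
  factors <- match.arg(factors, c("area", "sex", "age_group"),
                       several.ok = TRUE)
  if (length(factors) < 1) stopf("at least one environmental factor is required")
  followup <- match.arg(followup)
  for (th in c(geno, maf, hwe)) if (!is_prob(th))
    stopf("QC thresholds must lie in [0, 1]")
  if (prune_cutoff < 0 || group_threshold < 0)
    stopf("relationship thresholds must be >= 0")
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must lie in (0, 1)")
  if (is.null(simulate) && (is.null(bfile) || is.null(sample_file)))
    stopf("supply either `simulate` or both `bfile` and `sample_file`")
  structure(list(
    traits = traits, factors = factors, bfile = bfile,
    sample_file = sample_file, simulate = simulate, trait_h2 = trait_h2,
    transforms = transforms, geno = geno, maf = maf, hwe = hwe,
    prune_cutoff = prune_cutoff, group_threshold = group_threshold,
    alpha = alpha, followup = followup, out_dir = out_dir,
    seed = as.integer(seed), exam_year = exam_year
  ), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the \code{\link{run_config}} arguments; a
#' \code{simulate:} block mirrors \code{\link{sim_config}}.
#'
#' @param path YAML file path.
#' @return A \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(sim_config, raw$simulate)
  if (!is.null(raw$trait_h2)) raw$trait_h2 <- as.data.frame(raw$trait_h2)
  if (!is.null(raw$transforms)) raw$transforms <- unlist(raw$transforms)
  do.call(run_config, raw)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

simulate_pipeline_input <- function(cfg) {
  sc <- cfg$simulate
  G <- simulate_genotypes(sc)
  samples <- simulate_samples(sc)
  for (i in seq_along(cfg$traits)) {
    tr <- cfg$traits[i]
    h2g <- sc$h2_g
    h2ge <- sc$h2_ge
    fct <- "area"
    if (!is.null(cfg$trait_h2) && tr %in% cfg$trait_h2$trait) {
      row <- cfg$trait_h2[cfg$trait_h2$trait == tr, ]
      h2g <- row$h2_g
      h2ge <- row$h2_ge
      if ("factor" %in% names(row)) fct <- row$factor
    }
    sci <- sc
    sci$h2_g <- h2g
    sci$h2_ge <- h2ge
    sci$seed <- child_seed(sc$seed, "phenotype") + 1000L * i
    env <- encode_env(samples, fct)
    samples[[tr]] <- as.numeric(simulate_phenotype(G, env, sci)$y)
  }
  list(genotypes = G, samples = samples)
}

#' Run the full GxE heritability analysis
#'
#' Executes, in order: input (read or simulate), marker QC, phenotype
#' adjustment (age regression and z-scoring within area x sex strata), GRM
#' construction, relatedness pruning, per trait x factor REML with the
#' boundary LRT, Bonferroni control over the trait x factor family, optional
#' follow-up (per-SNP scan, genotype-group norms of reaction, bivariate
#' genetic correlation) for significant pairs with two-level factors, and
#' the with/without-interaction comparison of additive estimates. Every
#' stage writes its table under \code{cfg$out_dir}; a rerun with the same
#' configuration and seed reproduces all outputs.
#'
#' @param cfg A \code{\link{run_config}}.
#' @return An object of class \code{"run_summary"}: the per trait x factor
#'   results table, the Bonferroni threshold and significant pairs, the
#'   additive-estimate comparison per factor, follow-up result paths, and
#'   the configuration.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  if (!is.null(cfg$simulate)) {
    inp <- simulate_pipeline_input(cfg)
    write_plink(inp$genotypes, file.path(cfg$out_dir, "input"))
    write.table(inp$samples, file.path(cfg$out_dir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("input", "simulated %d individuals x %d SNPs (seed %d)",
              nrow(inp$genotypes$dosage), ncol(inp$genotypes$dosage),
              cfg$simulate$seed)
  } else {
    pl <- read_plink(cfg$bfile)
    samples <- read.table(cfg$sample_file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    inp <- list(genotypes = pl$genotypes, samples = samples)
    stage_log("input", "read %d individuals x %d SNPs from %s",
              nrow(pl$genotypes$dosage), ncol(pl$genotypes$dosage),
              cfg$bfile)
  }
  samples <- inp$samples
  missing_traits <- setdiff(cfg$traits, names(samples))
  if (length(missing_traits) > 0)
    stopf("trait column(s) not in sample table: %s",
          paste(missing_traits, collapse = ", "))

  qc <- qc_filter(inp$genotypes, miss_max = cfg$geno, maf_min = cfg$maf,
                  hwe_min = cfg$hwe)
  write_qc_report(qc$report, file.path(cfg$out_dir, "qc_report.tsv"))
  stage_log("qc", "retained %d of %d SNPs (geno %.3g, maf %.3g, hwe %.3g)",
            qc$report$retained, qc$report$n_input, cfg$geno, cfg$maf,
            cfg$hwe)

  samples <- adjust_traits(samples, cfg$traits, transforms = cfg$transforms,
                           exam_year = cfg$exam_year)
  write.table(samples, file.path(cfg$out_dir, "samples_adjusted.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("adjust", "adjusted %d trait(s) within area x sex strata",
            length(cfg$traits))

  A <- compute_grm(qc$genotypes)
  write_grm(A, file.path(cfg$out_dir, "grm"))
  keep <- prune_related(A, cutoff = cfg$prune_cutoff)
  A_pruned <- subset_grm(A, keep)
  writeLines(keep, file.path(cfg$out_dir, "unrelated_ids.txt"))
  stage_log("grm", "GRM on %d SNPs; pruning at > %.3g retained %d of %d individuals",
            qc$report$retained, cfg$prune_cutoff, length(keep),
            length(A$sample_ids))

  rows <- list()
  fits <- list()
  for (fct in cfg$factors) {
    env <- encode_env(samples, fct)
    env <- env[keep]
    attr(env, "env_name") <- fct
    for (tr in cfg$traits) {
      y <- setNames(samples[[paste0(tr, "_Z")]], samples$IID)[keep]
      fit <- gxe_heritability(y, A_pruned, env)
      fits[[paste(tr, fct, sep = ":")]] <- fit
      f <- fit$full
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, factor = fct, n = f$n,
        vg_vp = f$props[["V(G)/Vp"]], vg_se = f$se_props[["V(G)/Vp"]],
        vge_vp = f$props[["V(GxE)/Vp"]], vge_se = f$se_props[["V(GxE)/Vp"]],
        vg_vp_reduced = fit$reduced$props[["V(G)/Vp"]],
        lrt = fit$lrt$statistic, p = fit$lrt$p_value,
        converged = f$converged
      )
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  n_tests <- length(cfg$traits) * length(cfg$factors)
  threshold <- bonferroni_threshold(cfg$alpha, n_tests)
  results$significant <- results$p < threshold
  write.table(results, file.path(cfg$out_dir, "gxe_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("reml", "%d trait x factor fits; Bonferroni threshold %.3g (%d tests); %d significant",
            nrow(results), threshold, n_tests, sum(results$significant))

  followup_files <- character(0)
  do_pairs <- switch(cfg$followup,
                     none = results[0, ],
                     all = results,
                     significant = results[results$significant, ])
  for (i in seq_len(nrow(do_pairs))) {
    tr <- do_pairs$trait[i]
    fct <- do_pairs$factor[i]
    env <- encode_env(samples, fct)[keep]
    if (nlevels(droplevels(env)) != 2L) {
      stage_log("followup", "skipping %s x %s: factor has %d levels (need 2)",
                tr, fct, nlevels(droplevels(env)))
      next
    }
    y <- setNames(samples[[paste0(tr, "_Z")]], samples$IID)[keep]
    Gk <- qc$genotypes
    idx <- match(keep, Gk$sample_ids)
    Gk <- genotype_matrix(Gk$dosage[idx, , drop = FALSE], snps = Gk$snps,
                          sample_ids = keep)
    scan_tab <- gxe_scan(Gk, y, env)
    fp <- file.path(cfg$out_dir, sprintf("scan_%s_%s.tsv", tr, fct))
    write.table(scan_tab, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    followup_files <- c(followup_files, fp)
    nor_fp <- tryCatch({
      grp <- build_genotype_groups(A_pruned,
                                   threshold = cfg$group_threshold)
      nor <- reaction_norm_summary(grp, y, env)
      fp2 <- file.path(cfg$out_dir, sprintf("nor_%s_%s.tsv", tr, fct))
      write.table(nor, fp2, sep = "\t", quote = FALSE, row.names = FALSE)
      fp2
    }, error = function(e) {
      stage_log("followup", "norms of reaction unavailable for %s x %s: %s",
                tr, fct, conditionMessage(e))
      NULL
    })
    followup_files <- c(followup_files, nor_fp)
    lev <- levels(env)
    bv <- tryCatch({
      fitb <- bivar_reml(y[env == lev[1]], y[env == lev[2]], A_pruned)
      fp3 <- file.path(cfg$out_dir, sprintf("bivar_%s_%s.tsv", tr, fct))
      write.table(data.frame(Source = c(names(fitb$components), "rg",
                                        "se_rg", "logL"),
                             Value = c(fitb$components, fitb$rg,
                                       fitb$se_rg, fitb$logLik)),
                  fp3, sep = "\t", quote = FALSE, row.names = FALSE)
      fp3
    }, error = function(e) {
      stage_log("followup", "bivariate fit unavailable for %s x %s: %s",
                tr, fct, conditionMessage(e))
      NULL
    })
    followup_files <- c(followup_files, bv)
    stage_log("followup", "%s x %s: scan (%d SNPs with p < %.3g) and follow-up written",
              tr, fct, attr(scan_tab, "n_below_threshold"), 0.001)
  }

  comparison <- lapply(split(results, results$factor),
                       compare_vg_with_without_gxe)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  stage_log("done", "pipeline finished in %.1f s", elapsed)
  structure(list(results = results, threshold = threshold,
                 n_tests = n_tests,
                 significant = results[results$significant,
                                       c("trait", "factor", "p")],
                 comparison = comparison,
                 followup_files = followup_files,
                 fits = fits, config = cfg),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("GxE heritability pipeline: %d trait(s) x %d factor(s)\n",
              length(x$config$traits), length(x$config$factors)))
  cat(sprintf("Bonferroni threshold %.3g over %d tests\n", x$threshold,
              x$n_tests))
  tab <- x$results[, c("trait", "factor", "n", "vg_vp", "vge_vp", "lrt",
                       "p", "significant")]
  tab[, 4:7] <- signif(tab[, 4:7], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Compare additive estimates with and without the interaction component
#'
#' Pairs each trait's \eqn{V_G/V_P} estimate from the full (additive + GxE)
#' model with the estimate from the reduced (additive-only) model and
#' reports their Pearson correlation across traits (omitted with fewer than
#' 3 traits).
#'
#' @param results Either the results data frame of a
#'   \code{\link{run_full_analysis}} (columns \code{vg_vp},
#'   \code{vg_vp_reduced}) or a list of \code{"gxe_herit"} fits.
#' @return A list with \code{table} (trait, with, without) and
#'   \code{correlation} (NA when fewer than 3 traits).
#' @export
compare_vg_with_without_gxe <- function(results) {
  if (is.data.frame(results)) {
    tab <- data.frame(trait = results$trait,
                      vg_with_gxe = results$vg_vp,
                      vg_without_gxe = results$vg_vp_reduced)
  } else if (is.list(results) &&
             all(vapply(results, inherits, TRUE, "gxe_herit"))) {
    tab <- data.frame(
      trait = if (!is.null(names(results))) names(results)
              else seq_along(results),
      vg_with_gxe = vapply(results, function(f)
        f$full$props[["V(G)/Vp"]], numeric(1)),
      vg_without_gxe = vapply(results, function(f)
        f$reduced$props[["V(G)/Vp"]], numeric(1))
    )
  } else {
    stopf("`results` must be a results data frame or a list of gxe_herit fits")
  }
  r <- if (nrow(tab) >= 3) {
    cor(tab$vg_with_gxe, tab$vg_without_gxe)
  } else NA_real_
  list(table = tab, correlation = r)
}
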