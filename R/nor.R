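# Norms of reaction on GRM-derived genotype groups. Human genotypes cannot
# be replicated across environments, but individuals with high realized
# genetic relationships can be pooled into "genotype groups" whose mean
# phenotype per environment traces an approximate reaction norm.

#' Build genotype groups around GRM hubs
#'
#' Ranks individuals by the number of partners whose realized relationship
#' strictly exceeds \code{threshold}; the top \code{k} become hubs (ties
#' broken by input order). Each group is its hub plus all above-threshold
#' partners; any individual belonging to two or more groups is then removed
#' from all of them, so the returned groups are pairwise disjoint.
#'
#' @param A A \code{\link{grm_matrix}}, computed on the pruned (unrelated)
#'   sample set.
#' @param threshold Relationship threshold (default 0.020).
#' @param k Number of groups (default 3).
#' @return An object of class \code{"genotype_groups"}: a list of groups,
#'   each with \code{hub}, \code{members} (sample ids, post-exclusion), and
#'   \code{index}; pre-exclusion sizes are kept as attribute
#'   \code{"sizes_before_exclusion"}.
#' @export
build_genotype_groups <- function(A, threshold = 0.020, k = 3) {
  stopifnot(inherits(A, "grm_matrix"))
  if (!is_count(k) || k < 1) stopf("`k` must be a positive integer")
  v <- A$values
  adj <- v > threshold
  diag(adj) <- FALSE
  counts <- rowSums(adj)
  eligible <- sum(counts >= 1)
  if (eligible < k)
    stopf("only %d individual(s) have an above-threshold partner; cannot form %d groups",
          eligible, k)
  hubs <- order(-counts, seq_along(counts))[seq_len(k)]
  raw <- lapply(hubs, function(h) {
    members <- c(h, which(adj[h, ]))
    sort(unique(members))
  })
  sizes_before <- lengths(raw)
  membership <- table(unlist(raw))
  shared <- as.integer(names(membership)[membership >= 2])
  groups <- lapply(seq_len(k), function(g) {
    keep <- setdiff(raw[[g]], shared)
    list(hub = A$sample_ids[hubs[g]],
         members = A$sample_ids[keep],
         index = g)
  })
  structure(groups, class = "genotype_groups",
            sizes_before_exclusion = sizes_before,
            threshold = threshold)
}

#' @export
print.genotype_groups <- function(x, ...) {
  cat(sprintf("Genotype groups (GRM > %.3g):\n", attr(x, "threshold")))
  before <- attr(x, "sizes_before_exclusion")
  for (g in x) {
    cat(sprintf("  group %d: hub %s, %d member(s) (%d before overlap exclusion)\n",
                g$index, g$hub, length(g$members), before[g$index]))
  }
  invisible(x)
}

#' Reaction-norm summary for genotype groups
#'
#' For every (group x environment level) cell, the mean adjusted phenotype,
#' the standard error of the mean (sd / sqrt(n)), and the cell count.
#' Missing phenotypes are excluded per cell; cells with no observations are
#' flagged missing.
#'
#' @param groups A \code{\link{build_genotype_groups}} result.
#' @param y Named adjusted phenotype vector.
#' @param env Environment factor named by sample id.
#' @return An object of class \code{"nor_summary"}: a data frame with
#'   columns \code{group}, \code{env}, \code{n}, \code{mean}, \code{se}.
#'   Has \code{print} and \code{plot} methods.
#' @export
reaction_norm_summary <- function(groups, y, env) {
  stopifnot(inherits(groups, "genotype_groups"))
  if (is.null(names(y))) stopf("`y` must be named by sample id")
  env <- as.factor(env)
  if (is.null(names(env))) stopf("`env` must be named by sample id")
  rows <- list()
  for (g in groups) {
    for (lv in levels(env)) {
      ids <- g$members[g$members %in% names(env)[env == lv]]
      vals <- y[ids]
      vals <- vals[!is.na(vals)]
      n <- length(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g$index, env = lv, n = n,
        mean = if (n >= 1) mean(vals) else NA_real_,
        se = if (n >= 2) sd(vals) / sqrt(n) else if (n == 1) 0 else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nor_summary", "data.frame")
  out
}

#' @export
print.nor_summary <- function(x, ...) {
  cat("Norm-of-reaction summary (group x environment cell means)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (any(x$n == 0)) cat("note: cells with n = 0 are flagged missing\n")
  invisible(x)
}

#' Plot reaction norms
#'
#' One line per genotype group across environment levels, with +/- 1 SE
#' bars. Non-parallel (crossing) profiles indicate genotype-environment
#' interaction.
#'
#' @param x A \code{"nor_summary"}.
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, \code{x}.
#' @export
plot.nor_summary <- function(x, ...) {
  envs <- unique(x$env)
  grps <- unique(x$group)
  m <- matrix(NA_real_, length(envs), length(grps),
              dimnames = list(envs, grps))
  s <- m
  for (i in seq_len(nrow(x))) {
    m[as.character(x$env[i]), as.character(x$group[i])] <- x$mean[i]
    s[as.character(x$env[i]), as.character(x$group[i])] <- x$se[i]
  }
  graphics::matplot(seq_along(envs), m, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "environment",
                    ylab = "mean adjusted phenotype", ...)
  graphics::axis(1, at = seq_along(envs), labels = envs)
  for (j in seq_len(ncol(m))) {
    graphics::arrows(seq_along(envs), m[, j] - s[, j],
                     seq_along(envs), m[, j] + s[, j],
                     angle = 90, code = 3, length = 0.04, col = j)
  }
  invisible(x)
}

#' Interaction contrast of a two-environment reaction-norm summary
#'
#' The difference-of-differences of cell means between consecutive group
#' pairs; 0 for parallel profiles (no interaction).
#'
#' @param summary A \code{"nor_summary"} with exactly two environment levels.
#' @return Named numeric vector of contrasts, one per group pair.
#' @export
nor_interaction_contrast <- function(summary) {
  stopifnot(inherits(summary, "nor_summary"))
  envs <- unique(summary$env)
  if (length(envs) != 2L) stopf("interaction contrast needs two environments")
  grps <- sort(unique(summary$group))
  slope <- vapply(grps, function(g) {
    m <- summary$mean[summary$group == g]
    m[2] - m[1]
  }, numeric(1))
  out <- diff(slope)
  names(out) <- paste0("g", grps[-length(grps)], "_vs_g", grps[-1])
  out
}

#' Locus-specific norm of reaction
#'
#' Means, SEs and counts of the adjusted phenotype per (genotype class x
#' environment) cell for a single SNP, the classical single-locus reaction
#' norm view.
#'
#' @param dosage Dosage vector in {0, 1, 2, NA}.
#' @param y Adjusted phenotype vector.
#' @param env Environment factor with two levels.
#' @return Data frame with columns \code{genotype}, \code{env}, \code{n},
#'   \code{mean}, \code{se}; genotype classes absent in an environment are
#'   flagged with \code{n = 0}. A monomorphic SNP yields a single-class
#'   table with a warning.
#' @export
snp_reaction_norm <- function(dosage, y, env) {
  env <- as.factor(env)
  if (nlevels(env) != 2L) stopf("locus-specific NoR needs two environments")
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stopf("dosages must be 0, 1, 2 or NA")
  classes <- sort(unique(dosage[!is.na(dosage)]))
  if (length(classes) == 1L)
    warnf("monomorphic SNP: single-class reaction norm")
  rows <- list()
  for (cl in classes) {
    for (lv in levels(env)) {
      vals <- y[!is.na(dosage) & dosage == cl & env == lv]
      vals <- vals[!is.na(vals)]
      n <- length(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = cl, env = lv, n = n,
        mean = if (n >= 1) mean(vals) else NA_real_,
        se = if (n >= 2) sd(vals) / sqrt(n) else if (n == 1) 0 else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}
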