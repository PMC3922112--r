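---
title: "Estimating genotype-environment interaction heritability with gxeherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genotype-environment interaction heritability with gxeherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gxeherit` partitions the phenotypic variance of a quantitative trait
measured in a genotyped cohort into additive genetic, genotype-environment
interaction (G×E), and residual components:

$$ y = X\beta + g + ge + \epsilon, \qquad
   V = A_g\,\sigma^2_g + A_{ge}\,\sigma^2_{ge} + I\,\sigma^2_\epsilon . $$

Here $g$ collects the aggregate effects of all autosomal SNPs and $A_g$ is
the realized genetic relationship matrix (GRM) estimated from dosages,

$$ A_{jk} = \frac{1}{N_{jk}} \sum_i
   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}, $$

with $p_i$ the sample frequency of the counted allele and $N_{jk}$ the
number of SNPs non-missing in both individuals. The interaction term $ge$
has covariance structure $A_{ge}$, equal to $A_g$ for pairs of individuals
in the *same* environment (including the diagonal) and $0$ for pairs in
different environments. This masking encodes the assumption that
environment-specific genetic effects are drawn independently per
environment level: individuals sharing both alleles and an environment
share interaction effects, individuals in different environments do not.

The quantities of interest are the variance proportions
$\sigma^2_g/\sigma^2_p$ (SNP heritability) and
$\sigma^2_{ge}/\sigma^2_p$ (G×E heritability), with
$\sigma^2_p = \sigma^2_g + \sigma^2_{ge} + \sigma^2_\epsilon$.

Modeling assumptions worth keeping in mind:

* additivity on the analysis scale — interactions are scale-dependent, so
  phenotypes are transformed (e.g. log for right-skewed skinfolds) and
  adjusted *before* fitting;
* one environmental factor per fit — area, sex, and birth-year band are
  analyzed in three separate models, not jointly;
* environment levels are discrete and known without error;
* no shared-household environmental covariance — this is why close
  relatives are pruned before fitting (see below).

## Workflow and tunable parameters

The canonical order is: marker QC → phenotype adjustment → GRM →
relatedness pruning → REML per trait × factor → multiplicity control →
follow-up (per-SNP scan, norms of reaction, bivariate genetic
correlation). `run_full_analysis()` drives it from one configuration.

| Parameter | Default | Meaning |
|---|---|---|
| `miss_max` | 0.05 | remove SNPs with > 5% missing calls |
| `maf_min` | 0.01 | remove SNPs with minor allele frequency < 1% |
| `hwe_min` | 1e-6 | remove SNPs with Hardy-Weinberg exact p < 10⁻⁶ |
| `prune_cutoff` | 0.025 | drop one of each pair with GRM entry > 0.025 |
| `group_threshold` | 0.020 | GRM entry defining genotype-group membership |
| `alpha` | 0.05 | family-wise level for the trait × factor family |

Two of these deserve comment.

**Relatedness pruning.** A GRM entry of 0.025 is roughly half the
relationship of second cousins; pruning above it removes close relatives so
that the genetic variance is not inflated by phenotypic resemblance due to
shared environments. The pruner is greedy hub-first: repeatedly drop the
individual involved in the most above-cutoff pairs (ties keep the
earlier-listed sample). This retains more individuals than dropping an
arbitrary member of each pair. Note that the cutoff is meaningful only
relative to the sampling noise of the GRM, whose off-diagonal standard
deviation is about $1/\sqrt{m}$ for $m$ SNPs: with the full ~326k-marker
panels of a real cohort, noise is ~0.002 and the cutoff isolates genuine
relatives; with desk-scale simulated panels (m ≤ a few thousand) the
default cutoff sits inside the noise band and must be raised, which the
examples and tests do explicitly.

**Phenotype adjustment.** Each trait is regressed on age
($y = b_0 + b_1\,\mathrm{age} + e$) and the residuals standardized to
z-scores within each cohort-area × sex stratum (sample SD, $n-1$). Because
standardization is stratum-local, area and sex means are removed exactly,
and the mixed model needs no further fixed effects for them; the fitting
functions still include an environment indicator column in $X$ as a guard
for unbalanced simulated data, which is harmless when the phenotype is
already stratum-standardized.

## REML implementation

`greml()` maximizes the REML log-likelihood
$\ell(\theta) = -\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ by
average-information (AI) updates,
$\mathrm{AI}_{ij} = \tfrac12\, y'P K_i P K_j P y$, with gradient
$-\tfrac12[\mathrm{tr}(P K_i) - y'P K_i P y]$. Numerical choices:

* **Starting values**: each component gets
  $\hat\sigma^2_p/(\text{components}+1)$ — an equal split that is robust
  across the simulation grid.
* **Constraints**: variance components are floored at
  $10^{-6}\,\hat\sigma^2_p$. If an AI step would cross the floor, the
  offending components are clamped and the step re-solved for the free ones
  (active-set constrained Newton); expectation-maximization updates are the
  fallback when the constrained system degenerates. Naive EM-only fallback
  was rejected: its slow crawl near the boundary can trigger the
  log-likelihood tolerance far from the optimum.
* **Convergence**: relative log-likelihood change < 10⁻⁸ and component
  changes < 10⁻⁶·$\hat\sigma^2_p$, at most 100 iterations. Non-convergence
  flags the result rather than failing silently.
* **Standard errors**: inverse AI matrix; proportions by the delta method.
* **Degenerate structures**: if the AI matrix is numerically singular
  (e.g. $A_g = I$, making $\sigma^2_g$ and $\sigma^2_\epsilon$ jointly
  unidentifiable), the fit is flagged `flat_likelihood`.

**Boundary likelihood-ratio test.** The interaction component is tested by
comparing the full fit against the reduced model without $A_{ge}$
($\sigma^2_g$ stays free). Because the null value lies on the boundary of
the parameter space, the LRT null distribution is the 50:50 mixture of a
point mass at 0 and $\chi^2_1$, so $p = \tfrac12 P(\chi^2_1 \ge
\mathrm{LRT})$ and a statistic of 0 maps to $p = 0.5$. This mapping
reproduces printed cohort results exactly (statistic 11.68 → p ≈ 3.2×10⁻⁴;
4.38 → 1.8×10⁻²). Tiny negative statistics from finite convergence
tolerances are clamped to 0 with a warning.

**Bivariate fit.** `bivar_reml()` treats the trait in the two environments
as two traits on disjoint individuals; the stacked covariance has
per-environment genetic variances on the diagonal blocks, the genetic
covariance $\sigma_{g12}$ on the off-diagonal blocks, and per-environment
residuals. Residual covariance is structurally absent (nobody carries both
traits). The correlation is derived, $r_g = \sigma_{g12}/
\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$, never parameterized directly;
feasibility $|\sigma_{g12}| \le \sqrt{\sigma^2_{g1}\sigma^2_{g2}}$ is
enforced by projection. When the optimum lands on the $|r_g| = 1$ boundary
— common when the truth is there — projected steps alone stall slightly
short of the boundary optimum, so the fit is polished by AI-REML on the
fixed-correlation manifold $\sigma_{g12} = r\sqrt{\sigma^2_{g1}
\sigma^2_{g2}}$ with analytic $\partial V/\partial\theta$. The same
routine provides the constrained fit for `test_rg()`. For the null
$r_g = 0$ the constrained model simply omits the covariance structure and
the LRT reference is interior $\chi^2_1$; for $r_g = 1$ the null is on the
feasibility boundary and the $\chi^2_1$ reference is conservative, which
the output notes. A Wald test from the delta-method SE would be an
alternative; the LRT was chosen because it respects the feasibility
constraint near $|r_g| = 1$, where the Wald normal approximation is poor.

## The synthetic-data generator

`simulate_genotypes()` draws per-SNP allele frequencies uniformly on
[`maf_low`, `maf_high`] (default 0.05–0.5) and dosages as two independent
Bernoulli draws — Hardy-Weinberg sampling with no linkage disequilibrium.
`simulate_phenotype()` standardizes dosages by the *true* frequencies,
draws shared effects $u_i \sim N(0, h^2_g/m)$ and per-environment
deviations $v_i(e) \sim N(0, h^2_{ge}/m)$, and adds
$N(0, 1-h^2_g-h^2_{ge})$ residuals, so the phenotype variance is ~1 and
the interaction covariance matches the masked-GRM structure exactly.
`simulate_bivariate()` draws per-SNP effect pairs from a bivariate normal
with correlation `rg`. `spike_relatives()` rebuilds one member of a pair by
copying each of the partner's alleles with probability `copy_fraction`
(heterozygote allele order randomized so each allele is marginally
Bernoulli($p$)), giving expected GRM entries equal to `copy_fraction` —
calibrated material for the pruning rule.

Default scale: 2,000 individuals × 2,000 SNPs with a 40/60 two-level
environment split, echoing an unequal rural/urban cohort at desk scale.
At this size the REML standard error of a variance proportion is ~0.03 per
replicate, small enough that 30-replicate recovery runs resolve biases of
a few percent in minutes on one CPU. The generator standardizes by true
frequencies while the GRM uses sample frequencies; the small mismatch is
deliberate realism.

What the generator does *not* emulate: linkage disequilibrium (so
GRM-from-causal-SNPs precision is optimistic relative to real panels where
causal variants are tagged imperfectly), ascertainment, genotyping error,
population structure, and shared-household environmental covariance.
Passing recovery tests therefore demonstrate correctness of the estimator
under its own model assumptions, not robustness to the confounders real
cohorts face.

**Simulation conditions for the reference recoveries.** The univariate
recovery runs use the published decompositions directly: (0, 0.269) for
the genotype-area interaction and (0.179, 0.145) for genotype-sex. For
the bivariate recoveries no per-environment genetic variance is published,
so the generator uses $h^2 = 0.269$ per environment — the focal trait's
per-area genetic variance implied by its interaction decomposition
($\sigma^2_g + \sigma^2_{ge} = 0 + 0.269$) — for both the $r_g = 1$ and
$r_g = -0.26$ runs. One consequence is worth stating plainly: when the
true correlation sits at the feasibility boundary $r_g = 1$, estimates can
only deviate downward, so the mean of replicate estimates is expected a
few hundredths *below* 1 at this panel size (per-replicate SE ≈ 0.15–0.2).
The recovery band of ±0.10 around 1.00 is met only marginally; this is a
property of averaging boundary-constrained estimates, not an estimator
defect — the individual fits agree with direct likelihood maximization.

## Norms of reaction

Human genotypes cannot be replicated across environments, so
`build_genotype_groups()` approximates genotype replication by pooling
individuals with high realized relationships: individuals are ranked by
their number of GRM partners above `group_threshold` (strict inequality),
the top $k$ become hubs, each group is a hub plus its partners, and anyone
belonging to two or more groups is removed from all of them. Hub ranking is
computed once globally, the simplest reading of "top k most-connected
individuals"; recomputing after removing earlier hubs' members would be an
alternative but makes group membership depend on processing order.
`reaction_norm_summary()` then reports mean ± SE of the adjusted phenotype
per group × environment cell; parallel profiles indicate no interaction,
crossing profiles indicate it. This is an illustrative oversimplification
— groups share *genome-wide average* similarity, not identical genotypes —
and is reported as tables with an optional base-graphics plot, with no
claim of statistical efficiency.

## Per-SNP scan

`gxe_scan()` regresses the adjusted phenotype on dosage within each of two
environment levels and tests the slope difference with
$z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$ against a normal reference — the
convention of the standard G×E association tools; at cohort sample sizes
the difference from a t reference is negligible. Missing dosages are
dropped per SNP per stratum; monomorphic-within-stratum SNPs are flagged
with missing p-values rather than removed. The heritability-analysis
family (traits × factors) is Bonferroni-controlled with its own size —
49 traits × 3 factors gives the familiar 3.4×10⁻⁴ threshold — while the
SNP scan's multiplicity is the number of SNPs tested.

## Problem sizes used by the test suite

Unit tests run at n ≤ 500, m ≤ 5,000, sized so each check resolves its
target quantity within Monte-Carlo error (tolerances are set at ~3 MC
standard deviations). The recovery checks and the acceptance script use
the reference scale n = 2,000 × m = 2,000 with 20–30 replicates,
re-simulating phenotypes on a fixed genotype panel per setting, so
replicate variation reflects the effect and residual draws. The
REML-versus-grid-search
oracle checks run at n ≤ 25, where a 0.005-step grid over the proportion
simplex (with the overall scale profiled analytically) is exhaustive.

## Known limitations

* One environmental factor per model; joint multi-factor G×E is out of
  scope, as are dominance/epistatic relationship matrices and
  leave-one-chromosome-out GRMs.
* Binary traits are not transformed to the liability scale.
* BLUP prediction of individual genetic or interaction effects is not
  provided.
* The exact-test HWE filter treats all samples as one population; no
  founders-only or per-cohort option.
* Whether the published missingness filter is strict or non-strict
  inequality is not documented; strictly-greater-than is implemented.
* The pruning rule "remove one from each pair" does not specify which
  member; the hub-first greedy choice here retains more samples but can
  retain a slightly different set than other deterministic rules, shifting
  downstream n by a handful of individuals.
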