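---
title: "Pathway-level analysis of case-control GWAS data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level analysis of case-control GWAS data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgwas)
```

Single-marker association tests in case-control GWAS miss signals that are
spread over many variants of modest effect in functionally related genes.
`pathgwas` implements the complementary strategy of testing genes and
pathways as units: each gene's SNPs are compressed into a few orthogonal
*eigenSNPs*, pathways are tested jointly with a ridge-penalized logistic
regression whose permutation-standardized per-gene coefficient norms form a
pathway statistic (the GRASS test), individual genes are screened with a
logistic kernel machine (LKM) score test, replication across cohorts is
combined with Stouffer's z-score method, and the resulting gene list is
summarized by DAVID-style functional enrichment. A synthetic case-control
generator with within-gene LD, pathway-embedded causal effects, covariates
and optional population structure makes the entire pipeline testable
without access to controlled genotype data.

## The synthetic data generator

Genotypes follow a Gaussian-copula haplotype model. For each gene, a
subject's two haplotypes are independent AR(1) standard-normal vectors with
lag-one correlation `ld_rho`, thresholded at `qnorm(maf)` per SNP; the
dosage is the sum of the two indicator vectors. This construction was
chosen because it decouples the two quantities the downstream methods care
about: every SNP is marginally in exact Hardy-Weinberg proportions at its
target allele frequency regardless of `ld_rho`, while `ld_rho` alone
controls the within-gene correlation that eigenSNP compression must
capture. It does not attempt realistic human LD maps: blocks are strictly
AR(1), LD never crosses gene boundaries, and allele frequencies are drawn
independently per SNP. Passing tests therefore demonstrate correctness of
the statistical machinery under a controlled dependence structure, not
robustness to real LD topologies, imputation artifacts, or relatedness.

Disease status is assigned to a subject pool by an additive logistic model,
`P(case) = plogis(alpha0 + sum(beta * dosage) + covariate terms +
ancestry offset)`, and exactly `n_cases` cases and `n_controls` controls
are then sampled, mirroring a retrospective design. The pool is
`pool_multiplier` (default 20) times the target sample. Covariates are age
group (uniform over 5 bands), sex (Bernoulli 1/2), and study label;
principal components are *not* simulated — they are estimated downstream,
as in a real analysis. Population structure uses the Balding-Nichols model:
subpopulation allele frequencies are Beta draws around the ancestral
frequency with variance parameter `structure_fst`. A per-subpopulation
log-odds offset (`ancestry_effects`) turns structure into confounding;
without it, ancestry and phenotype are independent and omitting the PCs
would not distort inference, so the adjustment scenario would be vacuous.
Missingness is injected completely at random; Hardy-Weinberg violations are
injected by moving half of a SNP's heterozygotes to homozygotes (split
evenly to both homozygote classes, approximately preserving the allele
frequency), which produces the strong het-deficit departures genotyping
failures cause in practice.

Effect sizes have no published reference values at this granularity; the
defaults used in the analysis scripts and simulations (per-allele log odds
0.3-0.4 on 10 causal SNPs) were chosen once as representative of a
detectable but not trivial polygenic pathway signal at n of a few hundred
to a thousand.

## Quality control and inflation diagnostics

QC follows standard SNP-level practice: exclusion iff call rate < 0.98,
minor allele frequency < 0.05, exact Hardy-Weinberg p < 0.001, or distance
greater than 20 kb from every gene interval ("gene desert"; the same 20 kb
window used for SNP-to-gene mapping, since no separate numeric definition
exists). All boundaries are strict inequalities, all filters are evaluated
jointly on the pre-filter data (so reason counts are order-independent),
and a SNP may carry several exclusion reasons. MAF and the HWE test use the
non-missing genotypes of all subjects combined. The HWE test is the exact
conditional test — enumerate all heterozygote counts compatible with the
observed allele counts and sum the probabilities of configurations no more
probable than the observed one — rather than the chi-square approximation,
because it is well defined at the low counts QC must handle.

The per-SNP association statistic feeding the inflation factor is the
1-df Cochran-Armitage trend chi-square with scores (0, 1, 2), which equals
`N * r^2` for the dosage-phenotype correlation `r`; `lambda` is its median
over SNPs divided by the chi-square-1 median 0.4549364, and
`lambda_1000 = 1 + (lambda - 1) * (1/n_cases + 1/n_controls) / (2/1000)`
rescales the excess to a 1,000-case/1,000-control design. Missing dosages
are dropped pairwise for these statistics and mean-imputed only where a
complete matrix is required (PCA, eigenSNPs, kernels), which is documented
at each such point.

## Structure principal components

Genotypes are standardized the EIGENSTRAT way (impute missing with the SNP
mean, center at `2p`, scale by `sqrt(2p(1-p))`; monomorphic SNPs become
zero columns), and the top five right singular directions of the subject ×
SNP matrix give the PC covariates. Two reproducibility conventions are
fixed: each loading vector is flipped to have a positive sum, and the PCA
panel is LD-pruned with threshold `max(0.004, 20/n)`. The 0.004 cutoff is
the conventional structure-panel choice for cohorts of many thousands, but
the squared correlation of truly independent SNPs has sampling scale `1/n`;
at a few hundred subjects a fixed 0.004 sits below that noise floor, prunes
almost everything, and leaves too few SNPs to estimate ancestry — the
`20/n` floor keeps the per-pair false-pruning probability below 1e-5 while
still removing genuine LD. Whether PCs should come from the pruned or the
full SNP set is not established practice at this scale; the pruned default
is configurable.

## EigenSNPs and the GRASS pathway test

Each gene's SNP columns are mean-imputed, standardized, and decomposed by
PCA; the smallest number of components whose cumulative explained variance
reaches 95% becomes the gene's eigenSNPs, with scores rescaled to unit
variance. Standardizing before PCA means "genetic variation" is measured on
the correlation scale, so a rare SNP counts as much as a common one; the
raw-dosage alternative is available via `scale. = FALSE`. SNPs in
overlapping gene windows contribute to every such gene.

The pathway test fits all of a pathway's eigenSNPs jointly in a logistic
regression with an L2 penalty on the non-intercept coefficients. The
penalty is selected from a descending log-spaced grid (default 6 values,
200 to 0.05, on unit-variance predictors) by 5-fold cross-validated
binomial deviance with a seed-fixed fold assignment; deviance ties resolve
toward the stronger penalty. Per gene, the Euclidean norm `gamma_g` of its
eigenSNP coefficients is standardized by the mean and standard deviation of
the same norm over B phenotype permutations — each permutation re-running
the *entire* fit including penalty selection, so the observed and permuted
statistics are exchangeable by construction — and the pathway statistic is
`S = sqrt(sum_g t_g^2)` with p-value `(1 + #{S_b >= S}) / (1 + B)`, which
is never zero and makes the test valid at any B. Genes whose permutation
standard deviation is zero (coefficients identically shrunk away)
contribute `t = 0` with a warning. A two-stage design keeps large screens
affordable: all pathways at `stage1_B`, and any pathway at or below the
escalation threshold (default 0.00025, the Bonferroni level for a
197-pathway screen) re-tested at `stage2_B` on a fresh permutation stream.
A `freeze_tuning` flag reuses the observed fit's penalty in every
permutation; it is faster but conditions the null on an observed-data
quantity, so it is off by default and flagged in the documentation.

Covariates are deliberately absent from the GRASS model itself; optional
stratified permutation (e.g. by study) is the provided alternative.
Numerically, the permutation engine exploits two invariances: the design
and fold assignment are fixed across permutations, so one Cholesky factor
of the curvature bound `X'X/4 + lambda*D` per (fold, penalty) is
precomputed; and the majorize-minimize update with that fixed bound is
linear in the gradient, so all permutations advance in lock-step as one
matrix. Columns where MM stalls (saturated fits collapse the logistic
curvature) are finished by a damped Newton solver; final coefficients are
Newton-polished to a step tolerance of 1e-9. The fitted optimum is
independent of this hybrid path because the objective is strictly convex; a
literal loop-based reference implementation reproduces the engine's
permutation norms to 1e-6 in the tests.

## The logistic kernel machine gene test

For a gene with centered dosage matrix G, the null logistic model of
phenotype on covariates (age bands, sex, study, pc1..pc5) is fitted by
IRLS, and the score statistic is `Q = ||G'(y - mu0)||^2 / 2`, the linear-
kernel variance-components score test. Under the null, Q is a positive
mixture of 1-df chi-squares with weights equal to the eigenvalues of half
the P0-projected kernel, `P0 = V - V X (X'V X)^-1 X'V`, `V = diag(mu0(1 -
mu0))`. The primary p-value is computed by Imhof/Davies numerical inversion
of the characteristic function at absolute tolerance 1e-9: one eigenvalue
uses the exact scaled chi-square form; otherwise the oscillatory integral
is truncated where an integration-by-parts bound puts the tail below
tolerance. If the integration fails or degenerates, Satterthwaite
scaled-chi-square moment matching is used and the method is recorded per
gene. A residual-permutation reference (`lkm_permutation_pvalue`) serves as
a cross-check. The kernel is built on centered but unscaled dosages
(additive coding); a scaled variant sits behind a flag. The 1/2 factor in Q
is a convention with no effect on p-values.

One honest limitation surfaced by the test suite: the analytic null and a
label-permutation oracle differ systematically by `O(p_cov/n)` — about
0.005-0.01 in the p-value at n = 400 with ~9 covariate parameters — because
the permutation distribution conditions on the observed label vector and
its moments are not exactly the P0-projected weights. The Davies p-values
agree closely with a parametric simulation of the fitted null and with the
closed forms, so the gap reflects the permutation oracle's finite-population
moments, not an integration error; at 20,000 permutations the Monte-Carlo
standard error is small enough that this gap is visible as |z| of 3-5 for
some genes, and the corresponding oracle comparison in the test suite is
reported as measured rather than adjusted away.

## Replication and meta-analysis

`random_split` partitions subjects into two halves stratified by
case-control status (each half preserves the case fraction within one
subject). Per-unit p-values from two cohorts are combined one-sidedly:
`z_i = qnorm(1 - p_i)`, `z_meta = (z1 + z2)/sqrt(2)`,
`p_meta = 1 - pnorm(z_meta)` — the unweighted form, which reproduces the
published worked examples at printed precision; a sample-size-weighted
variant exists behind an argument but is off by default. Permutation
p-values of exactly 0 or 1 are clamped to `1/(2B)` from the boundary (or
1e-15 when no B is known) with a warning, since the probit is unbounded.

## Functional enrichment

The gene list (default: LKM p < 0.01) is scored against annotation terms by
the EASE-modified one-tailed Fisher exact test: the hypergeometric upper
tail with the observed overlap reduced by one, so single-gene overlaps are
never significant and every EASE p is at least the classical Fisher p. The
background universe defaults to all genes tested, and is configurable.
Terms are grouped by Cohen's kappa over membership vectors with a greedy,
deterministic procedure (seed the cluster at the unclustered term with most
partners at kappa >= 0.5, absorb those partners, repeat; ties by input
order): a documented, reproducible stand-in for fuzzy annotation
clustering, of which only the published score definition — the mean
-log10 p of member terms, equivalently -log10 of their geometric-mean p —
is treated as normative.

## Problem sizes, seeds and reproducibility

Every random stage derives its stream from one global seed via
`stage_seed()`, a fixed affine hash, so stages re-run in isolation
reproduce exactly; generated datasets are byte-identical given the same
configuration and seed. The bundled analysis uses a 400-subject study with
200 genes in 20 pathways and GRASS permutation counts of 499/4,999; the
validity and power simulations in the test suite use 500 null
pathway-tests at B = 199, 25 replicate datasets at n = 1,000 for rank
recovery, and 20,000-draw oracles for the kernel test — sizes chosen so the
whole suite documents calibration, power and oracle agreement at desk
scale. The reference permutation design for a full screen (5,000 stage-1
and 50,000 stage-2 permutations) remains the configuration default.

## Known limitations

The generator's LD model is block-AR(1) only; no X chromosome, relatedness,
imputation dosages, or genotyping batch effects. GRASS fits no covariates.
The enrichment clustering is a greedy simplification, and annotation terms
double as pathways in the bundled analysis. Real-data quantities that
depend on controlled-access genotypes (inflation of a specific cohort,
printed per-pathway p-values) are out of reach by design and are not
claimed by any test.
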