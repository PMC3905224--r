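---
title: "Methods: from cohort genotypes to gene-set enrichment evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cohort genotypes to gene-set enrichment evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogset)
```

## The inference chain

`cogset` implements a six-stage chain for asking whether a candidate set of
genes — for example the genes coding for a synaptic protein complex — is
collectively more associated with a quantitative trait than random sets of
genes, even when no single variant reaches genome-wide significance:

1. **Per-cohort single-SNP association.** Additive-model OLS of a
   standardized phenotype score on allele dosage, with optional covariates.
2. **Fixed-effect inverse-variance meta-analysis** of the per-cohort betas.
3. **LD-aware gene-based test.** Per gene, the sum of squared SNP Z-scores
   referred to a simulated multivariate-normal null with the SNPs' LD
   correlation matrix as covariance.
4. **Competitive gene-set enrichment.** A weighted Kolmogorov–Smirnov-style
   running sum over the genome-wide gene ranking, with a permutation null of
   random same-size gene sets and a GSEA-style FDR.
5. **Empirical validation** of discovery sets against 1000 random
   size-matched sets.
6. **Evidence combination** across cohorts by Stouffer's weighted-Z method,
   with Bonferroni correction of the discovery P.

A synthetic-cohort generator produces genotypes, phenotypes, annotation and
gene sets with the statistical structure the chain assumes, so every stage
is testable end to end without access to any real cohort.

## Phenotype scores

Cognitive batteries are summarized by the first unrotated principal
component of the battery's **correlation** matrix (tests are on different
scales; using the correlation matrix makes extraction scale invariant).
"Regression" scoring for PCA — loadings-weighted standardized tests scaled
by the inverse eigenvalue — equals the standardized component score, which
is what `gf_scores()` returns. The component is oriented so that the mean
test loading is positive; this makes the sign stable across resamples,
which matters because an arbitrary sign flip would invert every downstream
association.

Age and sex are removed by OLS residualisation (`residualize_age_sex()`),
returning standardized residuals that are exactly orthogonal to both
covariates. Two orders are supported, because real batteries have been
processed both ways: residualize the extracted factor (default) or
residualize every test before extraction (`residualize_after = FALSE` in
`pipeline_config()`). On the synthetic batteries the two orders correlate
above 0.98; the switch exists to mirror cohort-specific conventions, not to
change conclusions. Composite phenotypes (for example a general factor
built from a fluid factor and a vocabulary score) are per-sample means of
two standardized scores, re-standardized (`composite_mean()`).

Missing test scores are handled by listwise deletion; model-based factor
scoring with posterior sampling of incomplete batteries is out of scope.

## Quality control and association

`qc_filter()` applies the usual array thresholds, all configurable in
`qc_thresholds()`:

| filter | default | applies to |
|---|---|---|
| call rate | > 0.98 | all SNPs |
| minor allele frequency | > 0.01 | genotyped SNPs |
| Hardy–Weinberg exact P | > 0.001 | genotyped SNPs (hard calls) |
| imputation quality | > 0.3 | imputed SNPs (when a quality column exists) |
| imputed MAF | > 0.005 | imputed SNPs |

The Hardy–Weinberg test is the exact conditional test (two-sided: the sum of
probabilities of all heterozygote counts no more probable than the observed
one), computed in log space; an exact test remains well defined at the low
counts where the chi-square approximation fails. HWE is evaluated on
rounded hard calls because the conditional distribution is defined for
genotype counts, not dosages.

Association (`snp_association()`) is OLS of the phenotype on dosage plus
covariates, vectorized over SNPs via the Frisch–Waugh projection. Missing
dosages are mean-imputed per SNP. Monomorphic SNPs are emitted flagged with
`beta = 0, p = 1` rather than dropped, so summary files keep one row per
SNP. P-values are computed and stored alongside their base-10 logs so
extreme signals survive file round trips.

`ivw_meta()` pools cohorts with weights $w_i = 1/\mathrm{se}_i^2$, so
$\hat\beta = \sum_i w_i \beta_i / \sum_i w_i$ and
$\mathrm{se} = (\sum_i w_i)^{-1/2}$. Classical SE weighting is used, as the
plain reading of "inverse variance-weighted" (rather than sample-size
weighting). Alleles are harmonized to the first cohort reporting each SNP:
swapped alleles flip the sign and frequency, opposite-strand reports are
re-complemented when the SNP is not strand-ambiguous, and anything
irreconcilable is dropped with a warning. No heterogeneity statistics are
computed: the chain's downstream stages consume only the pooled Z.

## The gene-based test

SNPs belong to a gene if they fall within the gene body extended by 50 kb
on each side (`assign_snps()`, both window ends inclusive; a SNP inside two
windows counts for both genes). The window is anchored at the annotated
gene start/end, since the internal gene model does not carry UTR
coordinates.

For a gene with SNP Z-scores $z$ and LD correlation matrix $R$ (Pearson
correlation of dosages in the analysis cohort itself — the cohort is its
own LD reference), the statistic is $S = \sum_j z_j^2$. Under the null,
$z \sim \mathrm{MVN}(0, R)$, so the null law of $S$ is simulated by drawing
$u \sim \mathrm{MVN}(0, R)$ and the empirical P is the add-one-corrected
exceedance fraction $(1 + \#\{S^* \ge S\})/(B + 1)$ — never exactly zero,
with $B$ recorded per gene. The budget escalates through
$B \in \{10^3, 10^4, 10^5\}$ (configurable cap) while fewer than 100 null
exceedances have been seen, so only tail-extreme genes pay for large
simulations. Single-SNP genes take the SNP's two-sided P directly — the
exact 1-df case of the same statistic.

Numerical choices: $R$ is repaired to positive semi-definiteness by
clipping eigenvalues at $10^{-6}$ and rescaling to unit diagonal (duplicate
or perfectly correlated SNPs otherwise make the factorization fail);
the MVN factor is taken from the eigen-decomposition; per-gene seeds are
derived from `(master seed, gene id)` so results are independent of gene
order and stable under parallel or resumed execution.

Genes are ranked by $r = -\log_{10}(p)$, ties broken lexicographically by
gene id so the ranking is deterministic.

## Competitive enrichment

Walking down the ranked list, the running sum gains
$r_j^w / \sum_{\mathrm{hits}} r^w$ at each set member and loses
$1/(N - N_H)$ at each non-member; the enrichment score ES is the maximum
value attained. The exponent $w$ is 1 in the weighted (discovery-style)
analysis and 0 for the unit-weighted (replication-style) analysis; both are
exposed because published practice uses both. ES is one-sided for
top-of-list enrichment — depletion is deliberately not scored.

The null is generated by drawing random same-size gene subsets from the
ranking (equivalent to permuting gene labels). Permuting phenotypes instead
would require re-running the entire GWAS for each of the 15 000
permutations, which changes the question as well as the cost: a competitive
test asks about the set relative to other genes under the *observed*
ranking. The permutation P is add-one corrected, so its floor is
$1/(n_{perm}+1)$ — with the default 15 000 permutations, $1/15001$.

FDR follows the GSEA normalization: each score is divided by the mean of
the positive part of its own size's permutation null (NES); q is the
pooled-null tail fraction over the observed tail fraction, clipped to
$[0,1]$ and monotonized step-up (each set takes the smallest raw q among
itself and all less-enriched sets). With a single candidate set the
estimator degenerates and q is defined as the permutation P. Discovery
requires $P \le 0.05$ and/or $q < 0.25$.

**Empirical validation** re-scores 1000 random size-matched sets (each with
a reduced 2000-permutation budget — full budget is a flag) and reports the
fractions of random sets whose P and q exceed the observed ones; a set
validates when both fractions reach 0.95. Because each random set is
exchangeable with the permutation null, a null candidate set validates with
probability roughly 1 − 0.95, which the test suite checks by simulation.
**Leave-one-out** removes the set member with the largest ranking weight
and recomputes ES and P: signal that survives is not driven by one gene.

Candidate-set members absent from the ranking (for example genes with no
SNPs after QC) are dropped and counted; reported set sizes are intersection
sizes.

## Evidence combination

Per-cohort one-sided enrichment P-values are combined as
$Z = \sum_i w_i Z_i / \sqrt{\sum_i w_i^2}$ with $Z_i = \Phi^{-1}(1 - p_i)$
and $w_i = \sqrt{n_i}$ — the standard weighted-Z choice, invariant to
rescaling all weights. P-values are clipped to
$[10^{-300}, 1 - 10^{-16}]$ before the quantile transform (with a warning);
exact 0 or 1 is an error because the transform is infinite there. The
discovery cohort's P is Bonferroni-corrected (`bonferroni(p, m)`,
$m = $ sets × phenotypes tested) before combination. On the standard worked
numbers — a corrected discovery P of 0.04 (n = 3511) combined with
replication P-values 0.012 (n = 2062) and 0.371 (n = 670) — the combination
gives 0.0033. The same rule on the two replication cohorts alone gives
0.0168; a published value of 0.018 for that two-cohort combination is not
exactly recoverable under $\sqrt{n}$ weights, and the package reports the
computed value rather than guessing an alternative weighting.

## The synthetic-cohort generator

The generator is first-class, tested code; it defines the study conditions
under which the pipeline's calibration and power are demonstrated.

**Genome.** `n_genes` gene bodies (default length 30 kb) are laid
round-robin across chromosomes 1–22, 150 kb apart so the default ±50 kb
windows never overlap; an overlap mode places the second gene of each
chromosome 40 kb after the first to exercise multi-gene SNP assignment.
SNP positions are uniform inside gene bodies; target MAFs are uniform on
[0.05, 0.5] — common variants, as the QC thresholds presume.

**LD.** Haplotypes are generated per gene by thresholding a latent Gaussian
with AR(1) correlation $\rho^{|i-j|}$ (default $\rho = 0.8$) at the
MAF-matching quantile — a Gaussian-copula construction. Each individual is
the sum of two independent haplotypes. This gives reproducible, smoothly
parameterised within-gene LD that decays with distance and vanishes between
genes, which is the property the gene-based test must correct for. It makes
no attempt at coalescent realism: no recombination hotspots, no allele
frequency spectrum, no population structure or relatedness, no X
chromosome. Passing tests therefore show the statistics are correct under
blocky AR(1) LD, not that they are robust to every feature of real genomes.

**Phenotype.** The latent trait is
$g = g_{set} + g_{bg} + e$ with $g_{set}$ a random-weight sum of causal-set
SNP dosages rescaled to variance `h2_set`, $g_{bg}$ the background-gene
analogue at `h2_background`, and Gaussian $e$ making $\mathrm{var}(g) = 1$.
Battery test $t$ is $\lambda_t g + \sqrt{1-\lambda_t^2}\,\varepsilon +
\beta_{age}\,\mathrm{age} + \beta_{sex}\,\mathrm{sex}$ (defaults:
$\lambda_t = 0.7$, $\beta_{age} = -0.02$ per year, $\beta_{sex} = 0.1$; age
discrete uniform 40–79, sex Bernoulli(0.5)). The defaults for `h2_set`
(0.2 in the power studies) are chosen to give usable test power at
n = 2000, not to mimic any particular cohort's effect-size scale, which is
unknown.

**Seeds.** Every stochastic unit (cohort, phenotype, gene, permutation
batch, validation batch) draws from a seed derived by hashing the master
seed with the unit's key (`derive_seed()`). Adding a cohort or gene never
perturbs the streams of existing ones, and resumed pipeline runs reproduce
in-memory results bit-for-bit (stage TSVs are written with round-trip-exact
number formatting for the same reason).

## Calibration and power checks

The test suite demonstrates, at sizes chosen to keep a full run in the
tens of minutes on one core:

- **Null calibration, end to end:** with `h2_set = 0`, 500 genes, 2000
  samples and a 50-gene causal set, the causal set's enrichment P over 200
  replicate seeds is uniform (KS test at 0.01) with type-I error at
  $P \le 0.05$ inside the 95% binomial band. Reduced Monte-Carlo budgets
  (gene test $B = 1000$, 999 permutations) keep the 200 replicates tractable
  without biasing P-values — both engines are exact at any budget, budgets
  only set granularity.
- **Power:** with `h2_set = 0.2` concentrated in the 50-gene set, the
  median causal-set P over 20 replicates is below 0.05 while the
  size-matched decoy stays at the nominal rejection rate.
- **Oracle equivalence:** the gene test matches the $\chi^2_n$ survival
  function under identity LD within three Monte-Carlo standard errors at
  $B = 10^5$, and the running-sum score matches an exhaustive brute-force
  walk on every subset of rankings up to $N = 8$, both weight modes.

## Known limitations

- The competitive null is gene-subset permutation; correlated gene-level
  statistics between neighbouring genes (shared SNPs in overlapping
  windows) are not modelled in the null, matching standard GSEA practice.
- The LD reference is the largest analysed cohort; cross-cohort LD
  heterogeneity is ignored at the gene-test stage.
- Family-based cohorts, imputation, population-stratification estimation
  and X-chromosome analysis are out of scope; MDS or other stratification
  covariates are accepted as input columns.
- The FDR estimator is the GSEA ratio form; with very few candidate sets it
  is coarse, which is why the single-set case collapses to the permutation
  P and the empirical validation stage exists at all.
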