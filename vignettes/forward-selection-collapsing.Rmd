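---
title: "Data-adaptive forward-selection collapsing: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-adaptive forward-selection collapsing: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscollapse)
```

## The statistical model

`fscollapse` tests each gene for association between a quantitative trait
and the gene's mixture of common and rare variants.  The underlying
per-gene model is the ordinary single-predictor linear regression

$$ y_i = \beta_0 + \beta_1 s_i + \varepsilon_i, $$

where $s_i$ is a per-individual *collapsed score* summarising a member
set of variants and $y$ is the trait after covariate adjustment.  All
inference within a gene reduces to the model $F$ statistic with
$(1, N-2)$ degrees of freedom, or equivalently the slope's $t$ statistic
($F = t^2$).  The assumptions are those of OLS: independent individuals,
homoscedastic errors, and an additive per-allele effect of the collapsed
score.  The trait must be quantitative; case-control coding is out of
scope.

### Collapsing functions

For a member set $S$ and minor-allele counts $r_{ij} \in \{0,1,2\}$:

* **indicator**: $s_i = \mathbb{1}\{\sum_{j \in S} r_{ij} > 0\}$ —
  presence of any minor allele (the CAST coding);
* **sum**: $s_i = \sum_{j \in S} r_{ij}$ — proportion coding;
* **weighted sum**: $s_i = \sum_{j \in S} r_{ij} / w_j$ with the
  Madsen–Browning weight $w_j = \sqrt{n \hat q_j (1 - \hat q_j)}$,
  $\hat q_j = (1 + \sum_i r_{ij}) / (2 + 2n)$.

The frequency estimator uses a pseudocount so unobserved alleles still
receive a finite positive weight, and it pools **all** subjects: with a
quantitative trait there is no "unaffected" subgroup from which to
estimate frequencies.  Because the weights are phenotype-free they are
computed once per dataset and frozen; this keeps the permutation null
exchangeable and avoids recomputing weights in every permutation.

Composition is defined on member *sets*: `Collapse(S, g)` always
re-collapses the set $S \cup \{g\}$ from scratch, which makes the
operation well-defined and associative for every method (an incremental
definition on score vectors would be ambiguous for the indicator and
weighted sum).  In the indicator method the base common SNP enters as
presence/absence once the member set has at least two members; the base
is weighted like any other member in the weighted sum.

### Forward selection

Within a gene with common variants $x$ and rare variants $g$:

1. regress $y$ on each common variant's **raw** counts and take the
   variant with the largest $F$ as the base (step 1 deliberately does not
   collapse: a single raw 0/1/2 predictor is the natural seed, and the
   collapsing function first applies when the set reaches size two);
2. for each remaining rare variant, collapse it with the current member
   set and refit; keep the best candidate if its $F$ **strictly**
   exceeds the current $F$ (a tie stops the loop);
3. repeat until no candidate improves the fit or the pool is empty.

The gene's statistic is $FS = |t|$ of the final fit.  The absolute value
matters: under the null the greedy search can drive the slope in either
direction, and the permutation normalisation below needs a one-sided
quantity.

Determinism: candidate ties are broken toward the lowest variant index;
accepted variants leave the pool permanently (no backward elimination);
candidates whose collapsed score is constant (a saturated indicator is
common) are skipped rather than treated as errors, and a gene whose
common variants are all degenerate is reported as unusable (`NA`) rather
than falling back to rare-only collapsing.

### Genome-wide permutation calibration

Greedy selection optimises the statistic, so raw $FS$ values are inflated
and their null distributions differ across genes (more rare variants give
the search more room).  The package therefore re-runs the *entire*
selection path for every gene on $M$ permuted phenotypes.  One shared
permutation stream serves all genes in a given permutation — a
requirement for the per-permutation maximum to be a valid family-wise
statistic, and the reason permutations are drawn once per dataset rather
than per gene.  Each gene is then normalised by its own permutation
moments, $FS_{\text{adj},i} = (FS_i - \hat\mu_i)/\hat\sigma_i$ (the
$\hat\sigma_i$ uses the $M-1$ denominator), making genes comparable, and
the maxima $m_j = \max_i FS^*_{\text{adj},ij}$ yield the family-wise
global p-value $p_i = \#\{m_j > FS_{\text{adj},i}\}/M$.

Two numerical choices deserve note.  First, the strict `>` in the global
p-value is kept as the default, but it is anti-conservative by up to
$1/M$ and produces exact zeros that break $-\log_{10}$ plots; the
add-one estimate $(1 + \#)/(1 + M)$ is available via `smoothing = TRUE`
and is what the family-wise-validity test uses.  Second, genes whose
permutation standard deviation is zero are flagged degenerate, excluded
from the maxima and reported with $p = 1$ instead of being dropped
silently.

Alongside the family-wise global p, `perm_pvalues()` reports the
*marginal* per-gene permutation p-value
$(1 + \#\{FS^*_{ij} \ge FS_i\})/(M + 1)$.  The two answer different
questions: the global p controls the probability of any false positive
across the genome (its per-gene rejection rate at $\alpha$ is roughly
$\alpha/k$), while the marginal p is the per-gene calibrated test whose
type-I error at level $\alpha$ is $\approx \alpha$.  The type-I
calibration checks in this package use the marginal p; the family-wise
construction is verified by its own error-control property test.

## Phenotype adjustment

Confounders are handled upstream of the per-gene tests, once per trait:
one multivariate regression of the trait on all candidate covariates
keeps those with coefficient $p <$ `alpha_cov` (default 0.05).  Selecting
*associated* covariates is the only reading under which adjustment makes
sense; an `invert` flag exists for strict reproduction of screening rules
stated the other way around.  Screening uses the first phenotype
replicate only and the selection is reused for all replicates.  Ancestry
is captured by the top `n_pcs = 5` eigenvectors of the standardised
genotype covariance (centred by column mean, scaled by
$\sqrt{p(1-p)}$ with the posterior frequency estimate
$p = (1 + \sum_i g_{ij})/(2 + 2n)$ — the Eigenstrat convention), appended
unconditionally to the selected covariates.  The adjusted phenotype is
the OLS residual; no LD pruning is performed before the PCA and no
outliers are removed.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `rare_threshold` | 0.01 | allele frequency | rare iff $0 < \text{MAF} < 0.01$, strict boundary |
| `min_region_size` | 10 | variants | genes need enough members for collapsing to matter; at least one common SNP is additionally required (the base) |
| `n_permutations` | 1000 | count | resolves p-values to $10^{-3}$; the selection path is recomputed in full per permutation |
| `n_pcs` | 5 | components | conventional ancestry adjustment depth |
| `alpha_cov` | 0.05 | level | covariate screening |
| `smoothing` | FALSE | flag | add-one global p estimate |

MAF is always estimated jointly from all samples and folded to
$[0, 0.5]$; genotypes read from VCF or TSV are recoded to minor-allele
counts (columns with coded-allele frequency above 0.5 are flipped
$2-g$).  Monomorphic variants join neither member set: zero-variance
predictors are undefined in the regressions.  Missing genotypes are an
error by default; optional per-variant mean imputation exists because
silent zero-fill would bias MAF downward.  Multi-allelic VCF records are
rejected — the method is defined on biallelic SNPs.

## What the synthetic generator does and does not emulate

`sim_config()` / `simulate_genotypes()` / `simulate_phenotype()` produce
studies with the structure the method assumes: genes of
`variants_per_gene = 12` variants with 1–2 common members (MAF drawn
uniformly in 0.05–0.3) and a rare-dominated remainder (MAF 0.001–0.009),
300 individuals by default, genotypes Binomial(2, MAF) independent
across variants, and traits linear in a chosen subset of causal variants
plus optional covariates and Gaussian noise.  Genotypes and covariates
are fixed across phenotype replicates while noise is redrawn — the
fixed-genotype, replicated-phenotype design of community benchmark data
for this problem.  Monomorphic draws are rejection-sampled away so every
generated gene passes the analyzability filter; this conditions rare
MAFs slightly upward, which is irrelevant at the tested scales.

The generator deliberately omits linkage disequilibrium (the method is
LD-agnostic; variants are independent), haplotype structure, genotyping
error and missingness.  Passing tests on this generator therefore
demonstrates calibration and the selection mechanism under the model's
own assumptions; they do not certify behaviour under strong LD between
the base SNP and causal rares, under population stratification beyond
what the PC adjustment path is exercised with, or on real sequencing
data.

The misclassification scenario used by the power comparison fixes, a
priori: a weak common effect `beta_common = 0.15`, half the causal
gene's rare variants causal (`causal_rare_fraction = 0.5`) with
concordant sign and `beta_rare = 1` per minor allele (the
moderate-to-high effects posited for rare variants), unit noise.  In
this regime non-selective collapsing dilutes the signal with the
non-causal half, which is precisely the failure mode forward selection
exists to repair.

## Problem sizes used in the validation suite

The calibration check runs 200 genes × 25 null phenotype replicates at
$n = 300$ with $M = 200$ permutations per replicate and test — 15,000
pooled gene-level rejections per test, giving a binomial standard error
of about 0.3 percentage points on the 5% target.  The power comparison
uses 60 genes (3 causal) × 250 replicates at matched empirical
per-test significance (each test's $\alpha$ calibrated to a 5% pooled
null-gene rejection rate, mirroring the per-test $\alpha$ selection used
when tests with differently behaved p-values are compared), with a
one-sided exact binomial test on discordant causal-gene rejections.
Greedy-vs-oracle equivalence uses 200 random small genes at $n = 50$;
permutation-vs-enumeration uses $n = 6$ (720 relabelings).  These sizes
were chosen as the smallest designs at which the targeted effects are
statistically decidable.

## Implementation notes

The permutation and simulation hot path (greedy selection re-run for
every gene × permutation × replicate × method) is compiled C++ exposed
as `fs_stat_matrix()`.  Rare-variant columns are sparse, so candidate
fits are evaluated by $O(\text{carriers})$ updates of the running score
sums rather than full-length passes.  The pure-R
`run_forward_selection()` implements the identical algorithm
independently; the test suite asserts exact agreement of base choice,
selection order and traces between the two, and both against a naive
oracle that materialises every candidate score from scratch with
`lm()`.  Perfect fits (zero residual mean square) are flagged and given
$F = \infty$; near-tie acceptance decisions are exact because both
implementations compare statistics computed from identical score
vectors.  All randomness flows from user-supplied seeds through fixed
substreams (genotypes, per-replicate noise, per-replicate permutation
blocks), so every result in the package is bit-reproducible.

## Known limitations

* Genes without a usable common variant are skipped, not tested
  rare-only; the gene filter makes this explicit upstream.
* The permutation test assumes exchangeable residuals after adjustment;
  heteroscedastic or family-structured data would need a different null.
* Bonferroni correction for the baselines uses the number of analyzable
  genes, which is conservative under inter-gene correlation.
* With the strict-`>` default and finite $M$, global p-values of exactly
  0 occur; use `smoothing = TRUE` when ranking or plotting.
* The weighted-sum test can behave differently from the unweighted tests
  under trait-associated common variants (weights shrink their
  contribution only through $\sqrt{q(1-q)}$); calibrated per-test
  $\alpha$'s are the intended way to compare tests.
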