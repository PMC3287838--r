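# fscollapse

Gene-level association testing between quantitative traits and mixed
common/rare genetic variants, using a **data-adaptive forward-selection
collapsing strategy** with genome-wide permutation calibration.

## The problem

Burden (collapsing) tests aggregate the rare variants of a gene into one
per-individual score and test that score with a single degree of freedom.
Their power collapses when the member set is misclassified: mixing causal
and non-causal rare variants (or variants of opposite effect) dilutes the
aggregated signal. `fscollapse` addresses this by *selecting* the variants
that are collapsed:

1. **Base SNP.** Within a gene with `m` common and `n` rare variants,
   regress the adjusted trait `y` on each common variant's raw
   minor-allele counts and keep the SNP with the largest regression `F`
   statistic.
2. **Greedy accretion.** Collapse each remaining rare variant `g` with the
   current member set `S` under a collapsing function `Collapse(S, g)` and
   refit; accept the best candidate only if it strictly increases `F`.
   Repeat until no candidate improves the fit or no rares remain.
3. **FS statistic.** `FS = |t|` of the regression of `y` on the final
   collapsed score (for a single predictor, `F = t²`).

Three collapsing functions are supported for a member set `S` with
genotypes `r_ij` (minor-allele counts):

* indicator (CAST-style): `s_i = 1{ Σ_{j∈S} r_ij > 0 }`
* sum (proportion coding): `s_i = Σ_{j∈S} r_ij`
* weighted sum (Madsen–Browning): `s_i = Σ_{j∈S} r_ij / w_j` with
  `w_j = √(n q̂_j (1 − q̂_j))` and `q̂_j = (1 + Σ_i r_ij) / (2 + 2n)`
  estimated jointly from all subjects.

Because the selection step optimises the statistic, its null distribution
differs across genes and is inflated relative to a t distribution.  A
**genome-wide permutation test** re-runs the entire selection path for
every gene on `M` permuted phenotypes (one shared permutation stream for
all genes), normalises each gene's statistic by its own permutation mean
and standard deviation, `FS_adj,i = (FS_i − μ̂_i)/σ̂_i`, and derives
family-wise global p-values from the per-permutation maxima
`m_j = max_i FS*_adj,ij`.  Per-gene marginal permutation p-values are also
reported.

Non-selective baselines (`T_ind`, `T_sum` over all rare variants, `T_ws`
over all variants, `T_com` on the best single common variant) with
Bonferroni correction, phenotype adjustment (covariate screening,
Eigenstrat-style ancestry principal components, residual adjustment), a
synthetic-data generator and a type-I-error/power evaluation harness are
included.

## Worked example

Simulate a 40-gene study (300 individuals, 12 variants per gene, one
causal gene whose signal is split between a weak common variant and half
of its rare variants), write it in the package's TSV dialect, and run the
full workflow with 1,000 permutations:

```r
library(fscollapse)
cfg <- sim_config(n_individuals = 300, n_genes = 40,
                  causal_genes = "gene007", causal_rare_fraction = 0.5,
                  beta_common = 0.15, beta_rare = 1, seed = 20)
sim <- simulate_genotypes(cfg)
ph  <- simulate_phenotype(sim, cfg, 1)
write_genotypes_tsv(sim$genotypes, "geno.tsv")
write.table(sim$gene_map, "map.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = sim$genotypes$samples, Q1 = ph$y),
            "pheno.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

res <- run_analysis("geno.tsv", "map.tsv", "pheno.tsv", trait = "Q1",
                    n_permutations = 1000, n_pcs = 5, seed = 1)
#> genes: 40 mapped, 40 analyzable (>= 10 variants, >= 1 common)
#> selected covariates: (none); 5 PCs appended

top <- res$report[order(res$report$p_value), ]
head(top[top$test == "FS_ws",
         c("gene_id", "statistic", "adj_statistic", "p_value")], 5)
#>  gene_id statistic adj_statistic p_value
#>  gene007  5.803343      4.933706   0.000
#>  gene016  3.821544      2.092952   0.626
#>  gene038  3.342857      1.745515   0.866
#>  gene019  3.306329      1.416466   0.975
#>  gene028  3.342178      1.400669   0.976
```

The causal gene attains a raw FS statistic of 5.80 (`|t|` of the final
collapsed score), an adjusted statistic of 4.93 permutation standard
deviations above its own null mean, and a family-wise global p-value of 0
(none of the 1,000 per-permutation genome-wide maxima exceeded it; use
`smoothing = TRUE` for the add-one estimate 1/1001).  Every other gene is
far from significance — the `statistic` column shows how strongly the
selection step inflates raw |t| values (null genes reach 3.3–3.8), which
is exactly why the permutation normalisation is required.

The same workflow is scriptable from a shell via `exec/fscollapse`
(`fscollapse run --genotypes … --gene-map … --pheno … --out …` and
`fscollapse simulate …`).

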