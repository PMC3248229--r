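# landpop

Population structure, geography and climate analysis for crop landrace
collections genotyped at multi-allelic markers (microsatellites/SSRs).

Landrace collections — traditional, locally adapted crop populations —
carry population structure laid down by the spread of agriculture,
human selection and environmental adaptation. The classic analysis of
such a collection asks: how many genetic populations are there, which
accessions belong to which, and do the populations differ in
phenotype, geography and climate? `landpop` implements that entire
analysis for haploid genotypes, together with a synthetic-data
generator with known ground truth, so every stage can be validated by
parameter recovery.

## What it implements

**Admixture model (the core).** Each accession *i* carries a
membership row *q<sub>i</sub>* over *K* populations (rows sum to 1),
each population *k* has allele frequencies *p<sub>klj</sub>* at each
locus *l*, and each non-missing call arises by first drawing a
population of origin *z<sub>il</sub>* ~ Categorical(*q<sub>i</sub>*)
and then an allele ~ Categorical(*p<sub>z,l</sub>*). `gibbs_run()`
samples the posterior by a seeded Gibbs sweep over *Z*, *P*
(Dirichlet(λ) prior), *Q* (symmetric Dirichlet(α) prior) and the
admixture parameter α (Metropolis step, uniform prior), skipping
missing calls entirely. It reports posterior-mean *Q* and *P*, the
data log-likelihood trace, and the model evidence approximation
ln Pr(*X*|*K*) ≈ mean(lnL) − var(lnL)/2 used for K selection.

**Post-processing.** `align_q()` resolves label switching between
replicate runs by optimal (Hungarian) column assignment on the
correlation matrix, with the reproducibility rule that every matched
column correlate at *r* > 0.999; `detect_symmetric()` flags the
degenerate 1/*K*-everywhere solution that signals an overfitted *K*.
Three K-selection procedures: the ln Pr(*X*|*K*) curve, its rate of
change with a plateau report, and per-trait logistic-regression AIC of
binary phenotypes on the Q-matrix (`phenotype_aic()`).
`assign_populations()` gives primary populations with a ≥ 0.9
strong-membership flag, `trace_hierarchy()` follows how populations
split as *K* grows, and `phenotype_crosstab()` builds
population-by-trait count/percentage tables with Pearson χ² tests.

**Trees.** `allele_sharing_distance()` (1 − shared-allele fraction
over comparable loci) and `neighbor_joining()` (Saitou–Nei, negative
branches clamped with the deficit moved to the sibling), with Newick
export that tags strongly assigned leaves.

**Geography and climate.** Haversine great-circle distances on the
IUGG mean sphere (R = 6371.0088 km), population mean centres, standard
distances and standard-deviation ellipses, one-tailed Student tests of
mean-centre separation for every population pair, monthly
between/within-population climate variance F-ratios with a
permutation control, and a quasi-binomial regression of proportional
membership on climate covariates.

**Synthetic data.** `simulate_landraces()` generates genotypes under
the same admixture model the sampler fits (Balding–Nichols
F-divergence from an ancestral allele pool), MCAR missingness,
population-biased binary phenotypes, per-population geographic
ellipses and a latitude/season-driven climate surface — plus the true
*Q*, *P* and parameters for recovery tests.

## Worked example

```r
library(landpop)

cfg <- sim_config(n_accessions = 150, n_loci = 24, k_true = 3,
                  drift = 0.3, admixture_alpha = 0.05,
                  missing_rate = 0.096, seed = 42)
sim <- simulate_landraces(cfg)
dataset_summary(locus_summaries(sim$genotypes))[, 1:7]
#> # A tibble: 1 × 7
#>   n_loci mean_n_alleles min_n_alleles max_n_alleles mean_major_allele_freq
#>        24           6.21             3             9                  0.468
#>   mean_gene_diversity mean_pic
#>                 0.676    0.635

fit <- gibbs_run(sim$genotypes, k = 3, seed = 1)
fit
#> Haploid admixture fit: 150 accessions, k = 3, lnP(X|K) = -3736.2 (seed 1)
```

The 24 simulated loci carry 3–9 alleles each (mean PIC 0.64) with
~10% missing calls. Matching the posterior memberships to the
generator's truth shows the model recovered them:

```r
al <- align_q(sim$truth$true_Q, fit$Q)   # resolve label switching
mean(abs(sim$truth$true_Q - al$Qb_aligned))
#> [1] 0.0434

assignments <- assign_populations(fit$Q)
attr(assignments, "counts")
#> $n          [1] 150
#> $n_strong   [1] 131     # membership >= 0.9 in the primary population
#> $n_below_half [1] 0
```

A mean absolute membership error of 0.04 means the admixed fractions,
not just the labels, were recovered; 131/150 accessions are strongly
assigned. Downstream, the geographic and climate stages quantify how
distinct the populations' ranges and environments are:

```r
tests <- centre_separation_tests(sim$coordinates, assignments)
attr(tests, "n_significant")
#> p<0.05 p<0.01
#>      2      2          # of 3 population pairs (default ranges overlap)

climate_anova(sim$climate, assignments, month = 7)
#> # A tibble: 1 × 7
#>   month n_variables     F df_between df_within  p_value neg_log10_p
#>       7           9  7.57          2      1347 0.000536        3.27
```

A July F of 7.6 (−log10 p = 3.3) says between-population climate
variance is far above within-population variance: the simulated
populations are environmentally differentiated, as expected from their
latitude-separated ranges.

`run_pipeline(pipeline_config(...))` chains every stage — replicate
runs over a K range with the third-run reproducibility rule, K
selection, assignments, hierarchy, tree, geography, climate — and
writes each artifact plus a manifest to an output directory.

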