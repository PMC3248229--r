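---
title: "Methods: haploid admixture analysis of landrace collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haploid admixture analysis of landrace collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landpop)
```

`landpop` analyses population structure in haploid crop-landrace
collections typed at multi-allelic markers, and ships a generator that
produces data with known truth under the same model the inference
assumes. This vignette records the model, the tunable parameters and
their defaults, the numerical choices, and the design decisions taken
where the methodology was genuinely open.

## The admixture model and its sampler

Genotypes are one allele call per accession per locus (haploid: a
single homologous set, appropriate for selfing cereals where each
accession is represented by one consensus haplotype). The model:

* each accession $i$ has membership fractions $q_i \in \Delta^{K-1}$,
  with prior $q_i \sim \mathrm{Dir}(\alpha, \dots, \alpha)$;
* population $k$ has allele frequencies $p_{kl\cdot}$ at locus $l$,
  prior $\mathrm{Dir}(\lambda, \dots, \lambda)$, independent across
  $(k, l)$;
* a call arises by $z_{il} \sim \mathrm{Cat}(q_i)$ then
  $x_{il} \sim \mathrm{Cat}(p_{z_{il}, l, \cdot})$.

Missing calls contribute to no conditional — the model needs no
imputation, which is what makes marker dropout (common with
primer-site polymorphism) tolerable.

`gibbs_run()` iterates the four full conditionals / MH steps described
in its help page. Implementation notes:

* All randomness is drawn from R's RNG (also inside the compiled
  sampler), so `set.seed()`/the `seed` argument makes runs
  bit-reproducible.
* $\alpha$ is a single symmetric scalar, updated by a Metropolis step
  with a Normal(σ = 0.025) proposal reflecting at 0, prior Uniform(0,
  10). A scalar α matches the exchangeable-populations assumption;
  the small proposal keeps acceptance informative when α is near 0
  (nearly unadmixed collections).
* The frequency prior is the independent (uncorrelated) Dirichlet with
  λ = 1 by default. The correlated-frequencies alternative was not
  implemented; inference quality is instead validated directly by
  recovery tests against the generator truth (membership mean absolute
  error < 0.05 under the conditions below).
* Posterior **means** of Q and P over the thinned post-burn-in samples
  are reported (not a MAP state), matching how Q-matrices are
  conventionally consumed downstream.
* Default schedule is 5,000 burn-in + 20,000 sweeps thinned by 10.
  That is a desk-scale default chosen because, at a few hundred
  accessions and a few dozen loci, the chain's log-likelihood trace
  stabilises within the first few hundred sweeps; production-scale
  schedules (e.g. 200,000 + 1,500,000) are available through the same
  arguments.

The model evidence for K selection uses the standard approximation
$\ln \Pr(X \mid K) \approx \bar{L} - \mathrm{var}(L)/2$, with the
variance over the recorded trace taken with denominator $n$.

## Replicates, label switching and K selection

Population labels are non-identifiable across runs. `align_q()`
maximises the sum of per-matched-column Pearson correlations over
column permutations — solved exactly with a Hungarian assignment
rather than greedily, because near-ties between similar populations
can defeat greedy matching. Two runs are *reproducible* when every
matched correlation exceeds 0.999. The correlation is computed
per-population column (not on the flattened matrix), which is the
stricter reading. A column with zero variance cannot certify a match
and is reported as a diagnostic, never as reproducible.

`replicate_structure_runs()` encodes the replicate protocol: two runs
per K, a third attempted when the first two disagree.

Overfitted K shows up in two ways: replicate irreproducibility, and
the *symmetric solution* where every accession receives exactly $1/K$
in every population. `detect_symmetric()` tests
$\max_{ik} |q_{ik} - 1/K| < \mathrm{tol}$ with tol = 0.02 by default —
comfortably below the spacing between genuine membership values, while
tolerant of Monte Carlo noise.

Three K-selection procedures are provided and deliberately *not*
aggregated into a single "correct" K (the methods disagree
legitimately; the analyst reads them together):

1. the $\ln \Pr(X \mid K)$ curve itself;
2. its rate of change $L(K) - L(K-1)$, with an explicit plateau rule:
   the first K whose difference falls to ≤ 10% of the maximum
   difference. An eyeball-free rule is needed for testing; 10% is the
   point where, on generator data, the gain curve has visibly
   collapsed. Note the plateau key marks the first K *past* the last
   informative split, so the supported K is one below it — the
   pipeline applies that offset when choosing its focus K.
3. per-trait logistic AIC: trait ~ Q columns. Because Q rows sum to
   one, the design is collinear with the intercept; identifiability is
   restored by dropping the last Q column and keeping the intercept
   ($K$ parameters total). IRLS is run to gradient tolerance $10^{-8}$.
   Complete separation (possible when a trait is carried by one
   well-isolated population) is flagged and refit with a small ridge
   ($10^{-6}$) so a finite, comparable AIC is still reported, with a
   warning.

`assign_populations()` breaks argmax ties towards the lowest
population index (deterministic), flags memberships ≥ 0.9 as strong,
and counts primary memberships < 0.5 — note a 0.5/0.5 tie is *not*
below 0.5. `trace_hierarchy()` maps each population at K+1 to its
majority parent at K among accessions strong at both; the hierarchy
score is the fraction of such accessions whose K label equals the
majority parent of their K+1 label, which is exactly 1 when raising K
only ever splits populations.

## Distances and trees

The genetic distance is the allele-sharing distance
$d_{ij} = 1 - m_{ij}/c_{ij}$ (matches over comparable loci). The
metric was an open choice; allele sharing is the natural haploid
multi-allelic distance, and it increases monotonically with the
generator's divergence parameter (a tested property). Pairs with no
comparable locus are undefined and are a hard error at tree time —
silently imputing a distance could fabricate topology.

Neighbour joining is delegated to `ape::nj()` (Saitou–Nei), and the
result post-processed: NJ can emit negative branch lengths on
non-additive matrices, which are clamped to zero with the deficit
moved to the sibling branch, preserving sibling path lengths. On
additive matrices the tree reproduces the input distances exactly
(tolerance $10^{-9}$), which the tests exploit as an oracle. Newick
export tags strongly assigned leaves with `|popK`; tags never alter
topology.

## Geography

Distances are haversine great circles on a sphere of radius 6371.0088
km (IUGG mean). The mean centre is the planar arithmetic mean of
latitude and longitude — the convention of desktop GIS "mean centre"
tools; at European extents the divergence from a 3-D centroid is
negligible relative to the dispersions involved. The standard
distance is the RMS great-circle distance of members to the centre.
The standard-deviation ellipse comes from the eigen-decomposition of
the covariance of km-projected (equirectangular, local tangent plane)
offsets; axes are square roots of eigenvalues, rotation is the
major-axis bearing counter-clockwise from east, reported in [0°,
180°). At n = 2000 the generator's ellipse parameters are recovered
within 10%.

The mean-centre separation test is one-tailed Student's t with
$SE = \sqrt{SD_A^2/n_A + SD_B^2/n_B}$ built from the standard
distances and $df = n_A + n_B - 2$. The exact construction behind the
published form of this test is not recoverable; this two-sample-style
version is the documented default. It behaves correctly at the null
(identical populations give $t = 0$, $p = 0.5$) and has high power for
well-separated tight clusters.

## Climate

Monthly climate values (nine variables: mean/min/max temperature,
diurnal range, precipitation, wet-day frequency, frost days, vapour
pressure, cloud cover) are analysed by one-way ANOVA on population:
$F = MS_{between}/MS_{within}$, reported with $-\log_{10} p$. For a
variable *set*, each variable is z-scored across the included
accessions and the standardized (accession, variable) values pooled as
observations. Pooling was an open design choice; it weights variables
equally and yields one headline F per month.

One caveat discovered during validation and worth recording: under
label permutation the *pooled* F is not calibrated to 1, because one
accession's z-values are correlated across variables (they share the
accession's latitude), and with mixed-sign latitude slopes the cluster
means shrink — permuted pooled F averages ~0.7 under the generator
defaults. The randomization control is therefore run per variable
(one observation per accession), where the permuted F has mean ≈ 1;
that is also the form in which the control is conventionally stated.
`climate_anova_permuted()` documents this.

The membership-climate regression uses a quasi-binomial GLM (logit
link) of the proportional membership on climate summary covariates,
with the sequential deviance partition reported; collinear covariates
are dropped with a warning and the order-dependence of the partition
is documented.

## The synthetic generator: what it does and does not emulate

Defaults mirror a 651-accession, 24-locus European landrace study:
nine populations, ~9.6% missing calls, phenotype probabilities that
reproduce the strong population biases of such collections (two-rowed
ears predominating in some populations at > 90%, naked caryopses
majority in exactly one, winter habit majority in one), nine European
ellipse centres, and a climate surface linear in latitude with
sinusoidal seasonality.

Choices where the emulated study is silent:

* **Divergence model**: Balding–Nichols — population frequencies
  $\mathrm{Dir}(\pi \cdot (1-F)/F)$ around ancestral $\pi$, so a
  biallelic locus has $\mathrm{var}(p) = \pi(1-\pi)F$ (tested against
  that closed form). It is the standard generative counterpart of the
  correlated-frequencies prior. Default drift $F = 0.3$: moderate
  divergence at which 24 loci support reliable assignment of a few
  hundred accessions — the regime the analysis is designed for.
* **Admixture**: symmetric Dirichlet rows with α = 0.05, giving
  mostly-pure accessions with an admixed minority (roughly the
  strong-assignment fraction seen in real collections); α = 0 gives
  exactly unadmixed accessions with near-equal population sizes.
* **Missingness** is MCAR at a per-call rate. Real dropout is
  locus-correlated (primer-site polymorphism); MCAR is the simplest
  testable stand-in, and the rate is configurable per study.
* **Alleles per locus** defaults to 9 at every locus (a typical panel
  mean); the per-locus count is configurable rather than fixed,
  since real panels span roughly 2–26.
* **Phenotypes** depend only on the primary population, not on the
  admixed fractions — matching the granularity of crosstab analyses.
* **Climate** is a deterministic latitude + season surface plus iid
  noise; no longitude or oceanicity terms. That suffices to create
  the between/within-population variance signal, but it makes the
  simulated climate smoother than reality.

Consequently, passing recovery tests shows the *method* is correct and
well-calibrated under its own assumptions; it does not certify
performance on data with linked loci, locus-correlated dropout,
unmodelled inbreeding structure, or climate surfaces with
non-latitudinal structure.

## Numerical conventions and problem sizes

* Simplex-valued outputs are normalized exactly; tests assert unit row
  sums within $10^{-12}$ (generator) and $10^{-9}$ (sampler output).
* Gamma draws that underflow to zero at very small Dirichlet
  concentrations are renormalized to a vertex rather than producing
  NaN rows.
* Argmax ties, assignment ties and plateau ties are all broken
  deterministically (lowest index / smallest K).
* The test and acceptance workloads use 60–200 accessions × 24 loci,
  3–5 populations, and the 5,000/20,000 thinned-by-10 schedule; at
  these sizes a single run takes seconds and the full suite minutes,
  while leaving wide statistical margins on every assertion (e.g.
  membership recovery errors ~0.002–0.04 against a 0.05 bound).

## Known limitations

* Independent-frequency prior only; no linkage model; no prior
  population information; no diploid path.
* Single-chain runs per seed (replication is across seeds, as in the
  replicate-reproducibility protocol, not within-run parallel chains).
* The pooled climate F's permutation distribution is not centred at 1
  (see above); use the per-variable control.
* No bootstrap support on trees and no map/tree graphics beyond the
  provided ggplot helpers.
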