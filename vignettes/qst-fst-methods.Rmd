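---
title: "Methods: QST-FST divergence analysis for half-sib progeny trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QST-FST divergence analysis for half-sib progeny trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstfst)
```

## The question the package answers

Common-garden progeny trials plant open-pollinated (half-sib) families of
known geographic origin in shared environments, so that phenotypic
differences among origins reflect genetics rather than site plasticity. Given
such a trial — here modelled on a Norway spruce design with six genetic
clusters, two sites, randomized incomplete blocks and single-tree plots —
the package asks, per trait: *did this trait diverge among genetic clusters
more than neutral drift can explain?* The test compares the trait's
among-cluster differentiation QST with the genome-wide distribution of
per-SNP FST estimated from the mothers' genotypes. Under neutrality the two
are expected to be equal; QST above the bulk of the FST distribution
indicates divergent selection.

## Mixed models

All trait analyses are Gaussian linear mixed models fitted by REML (lme4),
separately per trait and cambial ring:

* **Model 1** — `Y = mu + site + B(site) + F + e` with block-within-site
  variance $\sigma_B^2$, family variance $\sigma_F^2$ and residual
  $\sigma^2$. Narrow-sense heritability is the half-sib intraclass
  correlation $h^2 = 4\sigma_F^2 / (\sigma_F^2 + \sigma_B^2 + \sigma^2)$:
  with ideal half-sibs the family variance is $V_A/4$, hence the factor 4.
* **Model 2** — adds fixed ABH (age at breast height, years — an inverse
  proxy of early growth rate), genetic cluster, and the ABH x cluster and
  ABH x site interactions. When the ABH x site interaction matters the data
  are split per site, dropping the site terms.
* **Model 3** — `Y = mu + ABH + G + B(site) + F + e`, where the cluster
  effect `G` is *random* with variance $\sigma_A^2$. QST is computed from
  this model.

Fixed-effect significance uses type-II Wald chi-square tests (car::Anova):
each term is tested after every other term except its higher-order
relatives, which makes the tests invariant to factor coding. A 6-level
cluster factor is tested on 5 degrees of freedom. Across the standard
battery of 6 traits x 11 rings = 66 fits, a Bonferroni cut-off of
$0.05/66 = 7.6\times10^{-4}$ is applied.

### Two QST conventions

`qst()` implements two denominators, and the difference matters:

* `method = "printed"` (default): $Q_{ST} = \sigma_A^2 / (\sigma_A^2 + 2\sigma_F^2)$,
  the form used in the published analysis this package reproduces.
* `method = "spitze"`: Spitze's definition uses twice the *additive*
  within-population variance; for ideal half-sibs $V_A = 4\sigma_F^2$, so
  $Q_{ST} = \sigma_A^2 / (\sigma_A^2 + 8\sigma_F^2)$.

Only the Spitze form has the neutral expectation $E[Q_{ST}] = F_{ST}$: with
Balding-Nichols drift at parameter $F$, the among-cluster variance of an
additive trait is $2F/(1-F)\,V_A$, and
$\frac{2F/(1-F)}{2F/(1-F) + 2} = F$ exactly. The printed form's neutral
expectation at $F = 0.1$ is about 0.31. The package therefore reports the
printed form for comparability and uses the Spitze form wherever neutral
calibration is the point (the end-to-end neutrality tests). We deliberately
do not guess which was intended where the two disagree; both are exposed.

## FST estimation

Per-SNP FST is the Weir-Cockerham (1984) variance-component estimator
$\hat\theta = a/(a+b+c)$, computed for every pair of clusters from allele
dosages (observed heterozygosity, sample-size-weighted components) and
averaged per locus over the pairs where it is defined. Loci with fewer than
two genotyped individuals in a population, or with $a+b+c = 0$, are
undefined and excluded. Negative per-locus estimates are legitimate and kept
in the per-SNP vector.

Two genome-wide means are reported, because the convention changes the
number: the **mean of ratios** (average of per-locus pair-averaged values)
and the **ratio of sums** (components summed over loci and pairs before the
ratio). At 20,000 simulated SNPs with 6 clusters of 50 mothers, the mean of
ratios under-estimates a Balding-Nichols target of 0.10 by about 18%
(per-locus ratio bias), while the ratio of sums is unbiased to within its
Monte-Carlo error; quantitative checks of the generator therefore use the
ratio of sums, whose delta-method standard error over loci is also reported.

The null reference for QST is the **positive part** of the per-SNP
distribution: non-positive values are discarded (not truncated to zero)
before taking quantiles, which preserves the shape of the attainable-
differentiation tail. The empirical p-value of a trait is the fraction of
positive per-SNP values at or above its ring-averaged QST (no +1 continuity
correction — the null is a genome-wide SNP set, not a permutation sample),
and the divergence verdict is QST exceeding the 95th percentile (type-7
interpolation). A variant including non-positive values is available behind
a flag.

## The synthetic-data generator

Because the original field data are not redistributable, every stage is
validated on synthetic data whose generating process matches what the models
assume:

* **Genotypes.** Ancestral allele frequencies uniform on [0.05, 0.95];
  per-cluster frequencies Balding-Nichols,
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so the expected among-cluster
  variance is $F\,p(1-p)$ and fixation is allowed; mothers drawn in
  Hardy-Weinberg proportions; missing calls injected independently (default
  10%). The default divergence target is $F = 0.05$, matching the
  genome-wide differentiation typical of the study system.
* **Phenotypes.** Drawn directly from the variance-component model the
  mixed models can see: cluster, block-within-site and family effects drawn
  once per trait and shared across rings, residuals per observation.
  Defaults on the mean-normalized trait scale
  ($\sigma_A^2 = 0.02$, $\sigma_F^2 = 0.03$, $\sigma_B^2 = 0.05$,
  $\sigma^2 = 0.165$) give heritability and QST magnitudes in the range
  reported for conifer wood traits. Cluster trait means follow a linear
  latitudinal gradient of +/-10%; ontogenetic trends are linear in ring
  number (the field data show trends but no stated functional form — linear
  is the minimal choice). The design defaults are 6 clusters, 20 families
  per cluster, 6 offspring per family per site, 2 sites with 20 and 23
  blocks, rings 3-13, and ABH generated once per tree from its own
  components.
* **Explicit-locus mode** (`simulate_neutral_study()`): for neutrality
  checks the cluster structure of the trait must arise from drift alone, so
  offspring traits are built from causal loci — one gamete from the mother,
  one from the cluster pollen cloud, i.i.d. Gaussian allelic effects — with
  no imposed cluster variance component.

What the generator does *not* emulate: spatial autocorrelation within
sites, paternal structure of open-pollinated seed (ideal half-sibs are
assumed, consistent with the heritability coefficient 4), linkage
disequilibrium among markers, selection during the simulated generations,
and realistic growth physiology. Passing tests therefore demonstrate the
statistical machinery, not robustness to these real-data features.

## Numerical and design choices

* REML fits use lme4 with derivative checks disabled; singular fits
  (a variance component at the zero boundary) are flagged, returned, and
  never hidden. Non-convergence is flagged with the optimizer messages kept.
* A random factor with a single observed level (e.g. one block) is dropped
  and its variance reported as 0 — it is inestimable and confounded with
  the intercept.
* Missing responses (and ABH, where it enters) are dropped listwise per fit.
* Genotype PCA mean-imputes missing dosages per locus and centers without
  variance scaling (the EIGENSTRAT-style convention; scaling is a flag).
  Sample filtering precedes locus filtering in the missingness filter, with
  strict inequalities at the thresholds.
* Multi-allelic VCF records are rejected by default; an opt-in mode keeps
  the first ALT allele and treats genotypes carrying other alleles as
  missing.
* Variance-component *recovery* in the validation suite is judged against
  the realized variance of the drawn effect vectors, not the parametric
  values: with 6 cluster levels, the parametric comparison is dominated by
  drift noise (a $\chi^2_5$ spread of about 40% median relative deviation)
  that no estimator can remove, whereas the realized variance is exactly
  what REML estimates.
* The Wald size check runs at 6 clusters x 50 families x 4 offspring: the
  type-II Wald chi-square is asymptotic in the number of family-level
  replicates, so calibration is only expected with many families per
  cluster.
* Validation problem sizes: 20,000 SNPs x 300 mothers for generator
  consistency; 2,160-observation designs (10 seeds) for recovery; 20
  replicates for neutral mean-equivalence and 200 replicate traits for the
  q95 calibration; 500 null fits for Wald size. These are the sizes at
  which the respective asymptotics are expected to hold.

## Known limitations

* **The q95 rule is anticonservative for polygenic traits.** A neutral
  *polygenic* trait's cluster effects are Gaussian in the many-locus limit,
  so its QST follows a scaled $\chi^2_5$ null whose upper tail is fatter
  than the empirical per-SNP FST distribution (which is additionally
  down-shifted by per-locus ratio bias). In our neutral simulations at
  $F = 0.10$ the nominal-5% rule rejects roughly 9-10% of neutral traits.
  Verdicts near the threshold should be read with this in mind; the
  empirical p-value is reported alongside the binary verdict for exactly
  this reason.
* QST intervals are not provided (no bootstrap over families); the
  empirical p-value quantifies position within the FST null only.
* The VCF writer emits minimal GT-only v4.2 records; rich INFO/FORMAT
  fields from input files are not preserved through a round trip.
* Filters follow the stated order (individuals before SNPs); other QC tools
  may break ties between simultaneous threshold violations differently.

## Reproducibility

Every stochastic entry point takes an explicit seed; `simulate_study()` runs
all stages under a single stream seeded from the configuration, and
identical configuration plus seed reproduces output byte-for-byte.
`run_pipeline()` writes per-stage TSV/JSON outputs and a manifest with MD5
checksums, the seed and the full configuration.
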