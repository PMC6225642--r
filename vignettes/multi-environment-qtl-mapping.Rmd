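---
title: "Methods: multi-environment QTL mapping and phenotypic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment QTL mapping and phenotypic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastiqtl)
```

`plastiqtl` analyses genotype-by-environment (G×E) structure in biparental
yeast crosses: segregant panels phenotyped under several fermentation
conditions, genotyped at dense biallelic markers. This vignette is the
package's account of the statistical machinery, the assumptions it rests on,
and the design choices made where more than one reasonable option existed.

## The experimental design being modelled

The canonical design is a cross of two homozygous diploid wine starters whose
meiotic progeny (homothallic, hence again fully homozygous) are phenotyped in
three conditions: white grape must shaken (`SB14_Sk`), red must shaken
(`M15_Sk`) and red must unshaken (`M15`). The `SB14_Sk` vs `M15_Sk` contrast
probes the grape-must matrix (GM); `M15_Sk` vs `M15` probes micro-oxygenation
(μ-Ox), since shaking controls the oxygen input. Each strain × condition cell
is typically measured in duplicate. Because segregants are homozygous,
genotypes take two classes (A = first parent, B = second parent), equivalent
to haploid coding; markers are named `CHR__CROSS__POS` with 1-based physical
positions.

## Kinetic traits from CO₂ curves

Cumulative CO₂ release (g/L, from vessel weight loss) is smoothed by local
polynomial regression — degree 2, tricube weights, neighbourhood the `span`
fraction of points, default **span = 0.45** — and seven traits are read off
the fitted curve: `lp` (h, first crossing of 2 g/L), `t35g`/`t50g`/`t80g`
(h, first crossings of 35/50/80 g/L **minus `lp`**), `V15_50` and `V50_80`
(mean release rate between the crossings of 15%→50% and 50%→80% of `CO₂max`)
and `CO₂max` (maximum fitted value).

Numerical choices:

* Threshold crossings use linear interpolation between grid points; if noise
  produces several crossings, the first wins. Thresholds never reached give
  `NA` rather than an extrapolated value.
* The phase rates are CO₂-native quantities multiplied by a configurable
  stoichiometric factor, default **2.045 g sugar per g CO₂** (180 g glucose →
  88 g CO₂), so that the printed units are a sugar consumption rate. Setting
  the factor to 1 recovers the CO₂ release rate. The 15/50/80% anchors are
  read as percentages of the CO₂ *amount*, not of a time, and the percentile
  crossing times are absolute (not lag-corrected) — two points on which
  reasonable conventions differ; both are isolated behind `extract_traits()`.
* Local regression has a boundary bias: with a degree-2 fit, a window that
  spans the lag phase *and* a long sampled plateau can push the fitted value
  at the first time points above the 2 g/L lag threshold. Extraction is
  therefore exact on noiseless curves (the package tests it against an
  analytic sigmoid to < 1%) but `lp` from heavily smoothed, long-plateau
  grids should be treated with care; monitoring that stops shortly after
  `CO₂max` is reached avoids the issue.

## Plasticity statistics

**Variance decompositions.** `decompose_variance()` fits
`y = m + E + U + U×E + ε` by sequential (type I) least squares with terms in
the order environment, unit, interaction, and reports each term's share of the
total sum of squares. The unit factor is the cross (LM1), the strain (LM2) or
a two-class QTL genotype (LM3). On the balanced designs this machinery is
meant for, type I, II and III sums of squares coincide, so the E-first order
is a presentation convention, not a modelling commitment. P-values are
classical F tests by default; a permutation option (response permutation,
sequential SS recomputed) exists because published analyses of such designs
often use permutation ANOVA, whose p-values differ but whose SS shares are
identical.

**Heritability.** `h² = (σP² − σE²)/σP²`, with σP² the variance of the
per-observation progeny values within one condition and σE² the **median**
across strains of the within-strain replicate variance. The estimate is not
clipped: negative values (replicate noise exceeding population spread) are
reported and flagged. Note a small-sample property of the median: with only
two replicates, the replicate variance is a 1-df scaled chi-square whose
median is ≈ 0.455 σ², so ĥ² is biased upward by construction in a duplicate
design. The package's parameter-recovery tests therefore run with ~10
replicates, where the median bias is below 3%; the estimator itself is kept
exactly as defined.

**Transgression.** A progeny clone is transgressive when its mean lies beyond
the higher parental mean + kσ or below the lower parental mean − kσ, with σ
the pooled parental replicate SD and **k = 2** by default — a conventional
noise margin; the original rule it abstracts is configurable through `k`.

**Phenotype distances.** Euclidean distance on per-condition z-scored strain
means. Because the kinetic traits are strongly mutually correlated, the
`kinetics_preset = "t80g"` option keeps only `t80g` of the timed traits when
whole-profile distances are wanted; zero-variance conditions are dropped with
a warning rather than contributing 0/0.

**Reaction norms.** Per strain and trait, the vector of condition means. The
distance `D_ij = |1 − corr(norm_i, norm_j)|` is 0 for parallel norms
(invariant to positive affine transforms of either norm) and 2 for
mirror-image norms. Flat norms make the correlation undefined; the edge rules
are: two flat norms are at distance 0, a flat norm is at distance 1 from any
varying norm. Clustering is partitioning around medoids on the precomputed
matrix, with k chosen by the best mean silhouette width over **k = 2..10**.
Silhouette is undefined at k = 1, so the degenerate "everything parallel"
case is handled by a fallback: if even the best silhouette is below 0.1, one
cluster is reported with a flag.

**Ternary interaction profiles.** For a called QTL, three LM3 fits quantify
its action: Q×E on the GM pair (`SB14_Sk`, `M15_Sk`), Q×E on the μ-Ox pair
(`M15_Sk`, `M15`), and Q on all three conditions. Each percentage is computed
with the environment sum of squares removed from the denominator — otherwise
traits dominated by the E main effect would be incomparable — and the three
percentages renormalised to sum to one give the ternary coordinates, with
F-test significance flags at α = 0.05.

## The multi-environment Haley-Knott scan

Observations are strain × environment replicate means (averaging duplicates
costs little information and halves the noise; replicate-level scanning would
require modelling the within-cell error separately). At every marker the scan
compares three nested least-squares models on the trait vector *y*:

* null: `y ~ E`
* additive: `y ~ E + q`
* full: `y ~ E + q + q×E`

where `q` is the conditional probability of the A allele given the observed
flanking markers (Haldane map function on cM distances, physical positions
converted at **0.4 cM/kb** by default — a typical *S. cerevisiae* genome
average, configurable on the map). At typed markers `q` is 0/1 and Haley-Knott
regression reduces to exact marker regression; the probability machinery only
matters at missing calls. The scan runs on observed markers rather than a
pseudomarker grid: at the marker densities these crosses produce (a few kb
between markers), interval positions add nothing.

`LOD = (N/2) log₁₀(RSS_reduced/RSS_model)` with N the number of observations;
`lod_interaction = lod_full − lod_additive` is the G×E signal. The engine
residualizes the genotype columns against the environment design once per
scan and evaluates the full-model quadratic form in closed form per marker,
falling back to a pivoted QR at rank-deficient (e.g. monomorphic) markers,
which are reported as LOD 0.

**Rank normalisation.** Phenotypes are rank-normal transformed
(`qnorm((rank − 0.5)/n)`, average ranks for ties) before scanning. The
transform is applied **within each environment** by default. The alternative
— transforming the stacked three-environment vector — mixes the environment
main effect into the ranks: with well-separated condition baselines, the
pooled quantile map compresses allele effects unevenly across conditions and
manufactures interaction LOD at genuinely constant-effect loci (in the
package's typing experiments, a constant QTL was typed interactive in every
run under the stacked transform and in none under the within-environment
transform). The stacked variant remains available via
`transform_scope = "stacked"`.

**Thresholds.** Genome-wide significance uses the permutation scheme of
Churchill and Doerge: strain identities are permuted against genotype columns
with each strain's environment block kept intact, preserving the E main
effect and the within-strain correlation under the null; the threshold is the
(1 − α) quantile of the per-permutation genome-wide maximum LOD, computed
separately for the additive, full and interaction LODs. The published
description of this procedure in the source literature says "5% FDR"; a
permutation test on the maximum LOD controls the family-wise error rate, and
that standard meaning is what is implemented. 1000 permutations is the
production default; the calibration experiments below use 100–200 to keep
runtimes short, which only adds Monte-Carlo noise to the threshold.

**Calling.** Markers above the additive or full threshold are chained into
loci by single linkage with a 30-kb gap tolerance (the stated rule defines
only the peak window; chaining is the natural completion), the peak is the
max-LOD marker, and the locus is typed I when its interaction LOD exceeds the
interaction threshold, A otherwise. The allele raising the trait is read from
the sign of the genotype coefficient on the raw scale. Kinetic-trait calls
within 10 kb merge into one locus assigned to the lowest-p trait
(single-linkage again, so a chain of 8-kb steps merges even when its ends are
16 kb apart); calls from two crosses colocalize when the same trait maps
within 20 kb. All windows are inclusive in base pairs.

## What the synthetic generator does and does not emulate

The generator exists so that every stage is testable without external data.
It emulates: 1:1 biallelic segregation with linkage along chromosomes
(no-interference Poisson crossovers, hence Haldane-consistent recombination
fractions between any marker pair), independent chromosomes, configurable
missing-call rates, the three-condition design with duplicate replicates,
planted QTLs with per-environment additive effects (equal effects = a robust
QTL, unequal = G×E), a polygenic strain deviate constant across environments,
Gaussian replicate noise, and logistic CO₂ curves parameterised by lag,
maximum rate and plateau, with truncated Gaussian weighing noise.

It does **not** emulate: crossover interference, segregation distortion,
aneuploidy or translocation-induced pseudo-linkage between chromosomes (a
translocation can be *imitated* by planting correlated QTLs on two
chromosomes but is not modelled mechanistically), heteroscedastic or
autocorrelated measurement error in the curves, non-Gaussian trait
distributions, or epistasis. Passing the recovery tests therefore shows the
estimators are correct and calibrated under the stated generative model, not
that real fermentation data meet those assumptions.

Defaults mirror the design scale of a typical study: ~95 strains, 3
environments, 2 replicates; map sizes are per-test choices. Where the
generator needed a value no design states (environment baselines, noise SDs),
they were fixed once at levels giving heritabilities in the 0.5–0.9 range
observed for fermentation traits, and not revisited.

## Validation experiments and their problem sizes

The acceptance script and the test suite recompute, from scratch:

* Haldane calibration of adjacent-marker recombination at n = 10 000
  segregants (maximum deviation in SE units, expected < 3);
* exact agreement (≤ 10⁻⁹) of the scan LODs with an independent brute-force
  per-marker `lm()` oracle, including missing-genotype instances;
* detection of a QTL explaining 20% of phenotypic variance in 20 seeded runs
  at 100 strains × 3 environments × 240 markers (expected ≥ 80% of runs with
  exactly one call within 30 kb of the planted marker);
* typing accuracy for constant-effect vs environment-specific QTLs at large
  effect size, 20 runs each (expected ≥ 90%);
* genome-wide false-positive calibration on 50 QTL-free datasets at 200
  permutations each (expected ~5%, judged against a 99% binomial band);
* heritability recovery, mean over 50 populations of 100 strains × 10
  replicates with generative h² = 0.75 (expected within 0.05);
* variance explained by a locus constructed to explain 25%;
* perfect recovery of two planted reaction-norm shapes by PAM;
* kinetic-trait extraction error < 1% against an analytic sigmoid inverted
  by an independent root-finder.

These sizes are the package's own validation design, chosen to make the
binomial/Monte-Carlo error of each check small relative to its tolerance.

## Known limitations

* The interaction LOD is compared to a permutation threshold computed under
  the global null (no genetic effect at all), not under "additive effect
  present, no interaction"; with very large additive effects this is mildly
  anticonservative for typing. The ternary LM3 profile provides the
  complementary, directly interpretable decomposition.
* Per-environment rank normalisation equates the marginal trait
  distributions across conditions, so purely multiplicative scale effects of
  the environment are absorbed rather than detected as G×E; this is the
  price of robust typing (see above) and matches the "non-parallel norms"
  notion of plasticity rather than the "different units" one.
* The heritability estimator's median-of-replicate-variances is upward-biased
  in duplicate designs (see above); comparisons across designs with different
  replicate numbers should use the same replicate count.
* `reproduce_published_analysis()` expects the original study's supplementary
  tables as TSV exports; those third-party files are not redistributed with
  the package, so the corresponding checks only run where the user supplies
  them.
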