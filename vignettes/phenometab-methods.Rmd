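---
title: "Models and methods behind phenometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenometab analyses drought-stress experiments that combine daily imaging
of plant growth with GC-MS leaf metabolite profiling. This vignette
explains the statistical models the package implements, the defaults and
why they were chosen, what the synthetic-data generator does and does not
emulate, and the numerical decisions a maintainer should know about. It
states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The experimental design the package assumes

Twelve genotypes are grown under a well-watered control regime and a
drought regime; plants are imaged daily (biomass as a voxel volume,
height, width) from day 1 to day 28 after the onset of drought (DAD), with
drought lasting until about day 24 and rewatering afterwards. Leaf
metabolomes are profiled at 7, 13, 22 and 28 DAD on destructively sampled
plants: five replicates per genotype per timepoint under control, and
5, 6, 7, 5 under drought (more replicates where stress-induced variance is
larger). Yield components (grain weight and number, spike and tiller
counts, grain geometry) are scored at maturity.

## Phenotype time-series QC

Imaging traits carry occasional gross errors (segmentation failures,
moved pots). The flagger works per plant and trait on days up to
`last_qc_day` (default 22; the sudden changes caused by rewatering are
biology, not error, so later days are never flagged):

1. A local polynomial regression over day with tricube weights on a
   nearest-neighbour span (`nn_span`, default 0.5; 0.55 for biomass). The
   local polynomial has degree 2: growth curves are strongly convex then
   concave, and a degree-1 local fit leaves lack-of-fit residuals larger
   than the measurement noise, which destroys outlier calibration. The
   fit uses lowess-style bisquare robustness iterations on *relative*
   leave-one-out residuals, so a spike cannot mask itself — not even at a
   series boundary where its leverage is high.
2. A confidence band of `conf_int_size` (default 5; 7 for biomass) times
   the local standard error. Imaging size traits have multiplicative
   noise — the residual scale grows roughly in proportion to plant size —
   so the local SE is modelled as a constant coefficient of variation: one
   robust (spike-trimmed, leave-one-out corrected root-mean-square)
   relative-noise coefficient per series, multiplied by the local fitted
   value, with a small absolute floor near zero fitted values.
3. Two flag-exclude-refit rounds (`rounds = 2`), cumulative flags: a
   point masked by a larger spike in round one is caught in round two.

Flagged data then pass a `sd_k = 2` filter per
genotype × trait × day × treatment cell (fresh mean and SD per step,
sample SD with n−1), and a plant is dropped for a trait when strictly more
than `drop_fraction = 20%` of its QC-window days are flagged. Post-harvest
traits get the same cell-wise rule once (k = 2 or 3 depending on the
experiment). Note an intrinsic property of k·SD rules: in a cell of n
values the largest possible standardized deviation is (n−1)/√n, so a 3-SD
filter cannot flag anything in cells smaller than 11.

## Heritability, loss of trait, ANOVA

Variance components come from the expected mean squares of the two-way
genotype × experiment ANOVA (method of moments): σ²_E = MS_E,
σ²_gxe = (MS_GxE − MS_E)/r, σ²_g = (MS_G − MS_GxE)/(re), negatives
truncated at zero. REML would also work; the closed-form MoM estimator is
transparent, fast, and exactly testable. Broad-sense heritability across
experiments is

H² = σ²_g / (σ²_g + σ²_gxe/e + σ²_E/(re)).

Drought stability is summarised per genotype as
Loss of trait [%] = 100·(1 − trait_drought/trait_control); the percent
scale is forced by the magnitudes such a statistic must reproduce (biomass
losses around 60%).

The genotype × treatment ANOVA is fixed-effects with interaction and Type
II sums of squares (via `car::Anova`), which handles the unbalanced
replication sensibly. The divergence onset day is the first day whose
per-day treatment effect is significant; by default significance must
persist on the next observed day, because with eight pre-onset days at
α = 0.05 a literal "first significant day" fires early in roughly a third
of null runs. Tukey HSD letters use the insert-and-absorb algorithm on the
pairwise significance relation, so letter sharing exactly encodes
non-significance.

## Metabolite preprocessing

The chain runs independently per sampling timepoint (retained feature
sets may differ between timepoints): blank filter (keep a feature iff its
mean leaf intensity is strictly greater than 2 × its mean blank
intensity; features absent from blanks are kept), presence filter (keep
iff observed in ≥ 80% of samples; zero counts as unquantified), imputation
of missing values with 1/5 of the per-feature minimum, removal of the
`floor(0.25 · n)` features with the highest RSD (sd/mean on the current
intensities; infinite RSD for zero means removed first; ties broken by
feature ID for determinism), per-sample median normalization, log10, and
Pareto scaling ((x − mean)/√sd; after it a feature's variance equals its
original SD). Every filtering step contributes one report row and the
counts telescope — n_in − n_removed = n_out at each step.

Two deliberate choices: the RSD filter defaults to a single global
computation per timepoint (a `within_groups` scope, which averages
within-treatment RSDs and so ignores treatment shifts, is available); and
fold changes are computed on the median-normalized pre-log intensities
(`intensity_norm`) while tests run on the final processed values — t
statistics are invariant to per-feature affine maps, so testing on Pareto
scores, z-scored rows or log values is equivalent.

## Differential accumulation and multivariate models

Per feature and timepoint: pooled-variance two-sample t-test
(drought vs control), BH FDR across the features of that timepoint,
volcano gating at FDR < 0.05 and |log2 FC| > 1. Two caveats the package
surfaces deliberately: the per-feature t-test treats replicates as
independent, so with genotype structure in both arms it is mildly
anti-conservative (the null-calibration tests therefore use the
exchangeable null — no treatment *and* no genotype effects — and run on
processed, log-scale data, where skewness does not inflate the size);
and zero-pooled-variance features get t = 0, p = 1 with a flag.

OPLS-DA codes the two classes as −1/+1 (centred), extracts `n_ortho`
(default 1) orthogonal-signal components — each from the current
y-predictive weight vector, removing the y-orthogonal part of its loading
— and fits one predictive PLS component on the deflated matrix. The
predictive score is exactly orthogonal to every orthogonal score; with
`n_ortho = 0` the model coincides with one-component NIPALS PLS-DA. VIP
is computed over the predictive component, vip_j = √p·|w_j| with ‖w‖ = 1,
so mean(VIP²) = 1 and VIP > 1 marks above-average contributors. The model
consumes the already Pareto-scaled matrix and does not rescale; PCA is
SVD with the sign of each component fixed so its largest-magnitude
loading is positive.

## Tolerance ranking and biomarker discovery

Genotypes are ranked per trait (rank 1 = best, average ranks on ties) and
aggregated by the product of ranks; the total rank orders genotypes by
ascending rank product. The product — unlike the mean — lets one
outstanding trait outweigh several middling ones, and the two aggregation
rules genuinely disagree on real rank tables, which is why the package
carries a regression test asserting the product rule.

For biomarkers, metabolite intensities at 22 DAD and phenotypes are
averaged per genotype and paired four ways (CC, DD, LC, LD; Loss pairs
share the same response with different predictors). The unit of analysis
is the genotype (n = 12): loss of trait exists only at genotype level.
The screen reports Spearman's ρ with its t-approximation p-value
(BH-adjusted within each dataset) *and* the OLS R² — the squared Pearson
correlation, deliberately distinct from ρ², as a rank-linear but
value-nonlinear pair makes obvious. The PLSR ranking partitions the 12
genotypes into 4 disjoint test folds of 3 by a seeded shuffle; each fold
fits NIPALS PLS regression (X and y centred, no rescaling) on the other
9 genotypes with the component count (≤ 3) minimizing inner 4-fold
cross-validated RMSEP, ranks features by |coefficient|, and the rank
product across folds gives the final ranking. With p ≫ n the coefficient
vector is noisy and out-of-sample prediction is weak even for a true
predictor; the rank product across folds is what stabilizes feature
*identification*, which is the quantity of interest.

Pathway over-representation is a plain one-sided hypergeometric test per
pathway against a user-supplied local annotation map, with BH FDR — a
transparent substitute for network-based enrichment, which needs a live
pathway graph and is out of scope.

## The synthetic-data generator

`simulate_metabolome()` draws log-normal intensities: per-feature baseline
log10 abundance U(3, 5), genotype deviations N(0, 0.15), replicate noise
on the log scale, and for designated responsive features a
treatment × timepoint log2 shift (default profile 0.5/1/2/1.5 at
7/13/22/28 DAD, alternating sign across features — effects ramp with
stress severity and persist partially after rewatering). Key calibration
choices, fixed at design time:

* **Noise heterogeneity.** Filler features receive noise-SD multipliers
  U(0.8, 4); designed (responsive and causal) features use multiplier 1.
  Real GC-MS panels span a wide per-feature RSD range — that spread is
  the entire reason a "remove the noisiest 25%" filter exists. With
  homogeneous noise that filter would delete a random quarter of the
  designed features (or preferentially the treatment-responsive ones,
  whose shifts inflate global RSD), which contradicts the design it is
  meant to emulate: reliably annotated metabolites sit in the
  well-measured part of the feature space.
* **Causal-marker module.** The markers coupled to the target trait share
  a bounded-uniform genotype factor (SD 0.35 on log10) plus small
  idiosyncratic deviations — a correlated metabolite module reflecting
  one underlying physiology, strongly differing between genotypes. The
  bounded distribution matters: with a Gaussian factor a single extreme
  genotype occasionally dominates the raw-scale RSD and trips the
  variability filter.
* **Missingness.** MCAR at 1% by default (a `censor` mode provides
  abundance-dependent left-censoring). The 1/5-minimum imputation turns
  every missing value into a large negative log-scale outlier; at
  several percent missingness those outliers corrupt genotype means
  enough to break any 12-genotype correlation screen, which real studies
  avoid by only screening well-quantified features.
* **Growth curves.** Three-parameter logistic per plant; drought
  suppresses post-onset incremental growth by a genotype-specific factor
  (mean ≈ 0.29, tied to the latent tolerance score) that sets in with a
  1.5-day exponential ramp — an abrupt rate change would be a
  non-physiological kink that any local-regression QC flags — calibrated
  so mean biomass loss at the end of drought is around 60%, diverging
  strictly after `onset_day` (default 9). Post-harvest yield traits
  shrink under drought with trait-specific sensitivities; the target
  trait additionally receives `coupling_strength` (default 8 trait units
  per log10 unit) times the summed causal-marker genotype-mean
  log-intensities.

`inject_outliers()` shifts random points by ±magnitude × local SD, where
the local SD is a per-series relative first-difference noise coefficient
times the local value — consistent with the value-proportional noise the
curves actually carry.

What the generator does **not** emulate: chromatographic artifacts,
retention-index drift, batch and run-order effects beyond a constant
factor, abundance-dependent variance within a feature, image segmentation
errors other than additive spikes, and genotype × environment structure
beyond a single latent tolerance axis. Passing recovery tests therefore
demonstrate that the algorithms do what they claim under the designed
statistical structure — not that any particular real dataset satisfies
that structure.

## Numerical choices and degenerate inputs

Deterministic tie-breaks everywhere (feature ID order in the RSD filter,
average ranks elsewhere); seeds control every random draw and are
surfaced in outputs. Constant features are left centred (flagged) by
Pareto scaling, zeroed by row normalization, skipped by the correlation
screen; constant responses are an error in PLSR. Zero medians, zero
normalization factors and all-missing features produce warnings or named
errors, never silent propagation. Series shorter than 6 observed days are
skipped by the QC flagger with a warning. The problem sizes used in the
test suite and acceptance script (200 features, 100 null datasets, 50
biomarker-recovery runs, 5 QC runs) were chosen to give stable empirical
rates on a single CPU.

## Known limitations

The per-feature t-test ignores genotype clustering (as does the analysis
convention it reproduces); the heritability estimator assumes balanced or
near-balanced replication; OPLS-DA is two-class only, with no Q²-based
component selection beyond permutation diagnostics; the ORA module does
not attempt network-aware enrichment; and the rank-product ranking has no
attached significance calibration — it is a screening statistic.
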