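---
title: "Measuring collinearity effects on species distribution models with virtual species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collinearity effects on species distribution models with virtual species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualsdm)
```

## The question

Bioclimatic predictor sets are strongly collinear: over a continental
extent a correlation-matrix PCA of the 19 standard bioclim variables
typically concentrates ~90% of the variance on four axes. Collinearity
inflates parameter uncertainty and destabilises fitted models, and the
most common remedy in distribution modelling — replacing the raw layers
by a few PCA score layers — changes the predictor set the model sees.
Whether that helps or hurts, and for which class of algorithm, cannot be
settled with real species, because the true range is never known.

`virtualsdm` implements the virtual-species route: build species whose
niche, suitability surface and realised range are fully known, sample
occurrence records from the known range, fit distribution models on raw
versus PCA-derived predictors, and score the binary predictions against
the truth. Everything — environment, species, sampling, fitting,
evaluation, statistics — is a deterministic function of one master seed.

## The virtual world

**Environment.** The generator simulates V independent Gaussian
white-noise fields, smooths each with a separable Gaussian kernel
(`spatial_range`, default 10 cells), *whitens* the smoothed fields over
the masked cells and mixes them by the symmetric square root of a target
correlation matrix. Whitening before mixing makes the empirical
cross-layer correlation exactly the target — smoothing drastically
reduces the effective sample size, so without whitening the empirical
correlations of a mixed stack would wander far from the target even on
large grids. Each layer ends standardised (mean 0, sd 1 over the mask).

The default target, `worldclim_like_corr()`, is a fixed 19 x 19 matrix
built from four variable blocks (sizes 8, 7, 2, 2; within-block r = 0.94,
0.94, 0.65, 0.30; between-block r up to 0.42; two layers sign-flipped
against their block, as temperature seasonality and annual range are in
real bioclim data). Its spectrum begins 10.50, 3.93, 1.54, 1.19, 0.70,
0.35, so exactly four eigenvalues exceed 1 (Kaiser–Guttman selects 4
axes), the 95%-cumulative rule selects 6, and the first axis carries ~55%
of the variance — the qualitative shape of a continental bioclim PCA.

**Climatic plateaus.** Smooth Gaussian fields alone make an unusable
world for narrow niches: values drift continuously, so almost no cell is
environmentally close to any centroid in 19 dimensions, and species
defined with 20% tolerance occupy a handful of cells. Real continental
climate is different: it is organised in large blocks of near-identical
conditions (biomes — the Amazon basin is a vast, climatically
near-uniform region). The generator therefore partitions the mask into
`n_regions` contiguous Voronoi regions (default 60) and shrinks every
field towards its region mean, keeping a fraction `region_jitter`
(default 0.12) of the local deviation. Because the partition is shared by
all layers, the plateaus survive the whitening/mixing step. The defaults
were fixed once, by requiring that the standard design be viable (all
30 default species end with at least the 50 occupied cells needed for
sampling, and wide-tolerance ranges dominate their narrow counterparts)
— not by reference to any downstream result.

**Mask.** An irregular, connected "continent" grown cell-by-cell from the
grid centre (`blob_mask()`, 60% fill by default), so edge effects and
irregular coastlines are present without any projection machinery. All
code works in (row, col) cell space; ESRI ASCII files are the interchange
format, with both `xllcorner` and `xllcenter` header dialects accepted on
read and corner always written.

## Virtual species

A species is a Gaussian niche in *raw* layer space: suitability
S(x) = exp(−½ Σ_k (x_k − μ_k)² / σ²_k), with σ²_k equal to a tolerance
fraction f of layer k's study-area variance (f = 0.2 "narrow", 0.6
"wide"), and S(μ) = 1 exactly so the optimum is always persistent. The
15 default centroids are chosen by k-means over the standardised cell
environments — a stratified stand-in for hand-picking biome-representative
conditions — and shared between the two tolerance classes, giving 30
species. The niche is *always* defined on the raw layers; PCA scores are
purely a predictor-set treatment.

The realised range is produced by a stochastic colonization–extinction
automaton on the suitability surface. Each iteration, every occupied cell
makes 3 dispersal attempts; an attempt draws a jump distance d uniform on
1..5 and a target uniform on the Chebyshev ring at exactly distance d (so
propagules can cross unsuitable barriers up to 4 cells wide); an
unoccupied masked target is colonised with probability equal to its
clamped suitability. Then every occupied cell — including cells colonised
this very iteration — survives with probability equal to its clamped
suitability. Clamping sets p = 0 below suitability 0.1 and p = 1 above
0.9, stabilising very poor and very good habitat. Colonisation precedes
extinction, so rescue effects operate. Three interpretation choices are
worth stating explicitly:

* the high clamp means *certain persistence once reached*, not
  unconditional occupancy of all high-suitability cells — dispersal
  limitation stays real;
* direction on the ring is uniform because only the jump-distance
  distribution is structurally constrained; the ring is the simplest
  geometry consistent with "d cells apart";
* newly colonised cells are subject to the same iteration's extinction
  test by default (`extinction_spares_new = FALSE` flips this reading of
  the rescue-effect rule).

The automaton runs 100 iterations by default (an optional plateau rule
stops early when the range size is stable); one realisation defines the
species' truth for the whole experiment, and prevalence is the occupied
fraction of the mask.

## Sampling, algorithms, evaluation

Occurrence samples are 50 cells drawn uniformly without replacement from
the occupied cells, 10 independent replicates per species; the 10,000
background cells are drawn once per experiment and shared across species
and algorithms (a per-fit redraw would add between-algorithm variance
without serving the comparison). Every random component draws from a
named substream of the master seed, so adding a species or algorithm
never perturbs the draws of the others.

Four algorithms sit behind one fit/predict contract, spanning the
simple-presence-only versus complex-background-learner contrast:

* **ES** — Envelope Score, a quantitative Bioclim: score = fraction of
  variables inside the training min–max envelope.
* **MAHAL** — Mahalanobis distance to the training mean with the sample
  covariance; when the covariance is numerically singular (reciprocal
  condition number < 1e−10 — e.g. 50 points on 19 collinear variables) the
  Moore–Penrose pseudo-inverse is used and recorded. The suitability
  transform 1/(1+d) is fixed for reproducibility; all downstream use is
  threshold-based, so any strictly decreasing transform is equivalent.
* **LQ_BG** — a ridge-penalised binomial presence-vs-background fit on
  linear + quadratic features standardised by background statistics
  (optional hinge features), the stand-in for the Maxent class of
  learners. The penalty path is fitted with decreasing lambda ending at
  the target (default 0.01) for solver stability.
* **KERNEL_BG** — a radial-kernel C-classification SVM
  (presence-vs-background, class weights inversely proportional to class
  size, sigma defaulting to 1/V), the stand-in for the SVM class. The
  background is subsampled to 1000 rows for the quadratic-programming fit
  (the incoming background is already in random order); the oriented
  decision value is min–max rescaled to [0, 1] per prediction surface.

These two learners are deliberately *not* reimplementations of Maxent or
OpenModeller; they reproduce the algorithm-class contrast with fully
inspectable, dependency-light fits.

Binary maps use the `>=` convention throughout. Two threshold rules are
computed per fit: the **balance** threshold maximising
sensitivity + specificity against the true occupancy (ties broken towards
the smaller, more inclusive threshold), and **LPT**, the minimum predicted
value over the training presences (zero training omission by
construction). Metrics are sensitivity, specificity, TSS, underprediction
UP = FN/(TP+FN) and overprediction OP = FP/(TP+FP); the alternative
false-positive-rate reading of overprediction is available as
`op_formula = "fpr"`. Ratios with zero denominators propagate as `NA`,
never as 0.

## The factorial experiment and its statistics

`run_experiment()` crosses species (30) x predictor set (RAW, PCA4 =
Kaiser count, PCA6 = 95%-cumulative count) x algorithm (4) x replicate
(10) x threshold rule (2) and emits one tidy row per combination, with a
manifest of seeds, axis counts and exclusions. A species whose range
cannot support the occurrence sample is excluded with a logged reason —
never silently.

Three analyses mirror the study design:

* `ancova()` — response ~ prevalence + ENV * ALG * TOL with sum-to-zero
  coding and Type-II sums of squares (robust to the mild imbalance
  exclusions cause; Type I/III are options). The published software and
  SS type are unknown, and the F values depend on the environment data
  anyway, so only the degrees-of-freedom structure is comparable across
  studies: the paper-shaped 4500-row design leaves 4469 error df.
  Prevalence's contribution is summarised as partial eta-squared.
* `tss_stability()` — the variance of TSS across occurrence replicates
  per species x algorithm x predictor set, averaged over species with a
  t-based 95% CI (n = number of species; tolerance classes pooled).
* `range_size_regression()` — OLS of predicted on true range size pooled
  over species x replicates per algorithm x predictor set x rule.
* `species_residual_summary()` — per-species ANCOVA residual means with
  t CIs, the "idiosyncrasy" diagnostic.

Each result type has `tidy()`/`glance()` and an `autoplot()` display.

## Problem sizes and numerical choices

The default grid is 150 x 150 with a 60% mask (~13,500 cells), which
keeps the full factorial — 7,200 evaluation rows including ~1,800
penalised-likelihood and ~1,800 SVM fits with surface predictions —
around ten minutes on a single core; the unit-test suite uses 40–100 cell
grids and completes in a few minutes. Other numerical choices: sample
(n−1) variance everywhere, including the PCA standardisation; eigenvector
signs fixed so each axis' largest loading is positive; the balance
threshold scans all unique predicted values with a single cumulative
sweep; tiny negative squared Mahalanobis distances (< 1e−8) are clipped
to zero; degenerate (zero-background-variance) features are dropped with
a warning.

## What passing tests do and do not show

The generator reproduces the *structure* of the real study — collinearity
spectrum, spatial autocorrelation, biome-like plateaus, viable narrow and
wide species, range sizes spanning an order of magnitude — but not every
*magnitude*. In particular, in this synthetic world the occupied ranges
are environmentally compact and absences are environmentally distant, so
simple presence-only models binarised against the known truth make far
fewer omission errors than they do on real continental data, where
fine-grained within-range climate variation erodes 50-point envelopes.
The acceptance suite keeps the corresponding real-data-level omission
check in place and failing honestly rather than degrading the generator
to manufacture errors. Likewise, true range sizes at the default extent
span only about one order of magnitude, so the pooled predicted-vs-real
range-size regressions have far less between-species variance to explain
than on a real continent and their R-squared values sit well below
real-data levels (they rise monotonically as the grid grows). Conclusions about the *ordering* of algorithms and
predictor sets transfer with more confidence than any absolute error
rate. Non-Gaussian response shapes, biased sampling schemes, biotic
interactions and temporally varying environments are all out of scope.
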