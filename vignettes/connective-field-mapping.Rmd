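---
title: "3-D connective field mapping: model, metrics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3-D connective field mapping: model, metrics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A connective field describes *where* and *how broadly* a voxel in one brain
region (the **seed**) connects within another region (the **mapping**
region). For every seed voxel, its residualized BOLD time course is
correlated with every mapping voxel's time course; the correlations are
Fisher-z transformed (`atanh`, variance-stabilizing) into a connectivity
profile over the mapping region. That profile is then summarized by a 3-D
isotropic Gaussian

$$ g_v(x, y, z) = \frac{1}{\sigma^3 (2\pi)^{3/2}}
   \exp\!\left(-\frac{(x-x_0)^2 + (y-y_0)^2 + (z-z_0)^2}{2\sigma^2}\right), $$

with three location parameters $(x_0, y_0, z_0)$ — the preferred locus of
connectivity — and one spread parameter $\sigma$. The parameters are
estimated by minimizing the *correlation distance* between the z profile
and the Gaussian density evaluated at the mapping voxels,
$1 - \mathrm{cor}(z, g)$. Because correlation is scale- and
offset-invariant, the fit depends only on the profile's spatial *shape*:
multiplying all z values by a positive constant changes nothing, and
shifting both regions by an integer offset shifts the fitted center by
exactly that offset.

The fitted Gaussian doubles as an encoding model: the predicted seed time
series is the weighted sum of mapping activity,
$p_v(t) = \sum_{x,y,z} A(x,y,z,t)\, g_v(x,y,z)$, z-scored. `evaluate_fit()`
validates a map by comparing each voxel's *matched* prediction-data
correlation against the *mismatched* correlations with every other voxel's
prediction.

### Coordinates

All computations run in 0-based voxel-index space; the NIfTI affine is
carried for I/O and reporting only. On the near-isotropic grids this method
targets (3-4 mm isotropic acquisitions), index and millimeter space differ
by a global scale that the isotropic Gaussian and every downstream rank
statistic ignore. `cf_fit(coord_space = "world")` converts through the
affine first, for strongly anisotropic data.

### ROI-mean removal

By default the regional mean time course is subtracted from every voxel of
both regions before correlation, so connectivity is not driven by the
shared regional signal. One documented exception: on a *perfectly*
convergent synthetic pair — every seed voxel connected to the same locus —
the regional mean *is* the entire connectivity signal, and removing it
leaves pure noise. The convergence validation therefore runs with
`demean = FALSE`; real data never exhibit this exact degeneracy, and
mean removal remains the default everywhere.

## Fitting: initialization, bounds, multi-start

Optimization is box-constrained (L-BFGS-B): centers are bounded by the
mapping region's coordinate extremes, and $\sigma$ lies between machine
epsilon and the smallest axis range. The canonical initialization — the
location of the maximum z value, with $\sigma$ at machine epsilon — is
always one start. Because that start sits in a flat, degenerate corner of
the objective (an epsilon-width Gaussian correlates with nothing), we add
a coarse multi-start over $\sigma \in \{0.5, 1, 2, 4\}$ voxels and keep the
best objective; the returned objective never exceeds its value at any
initialization. A profile with zero variance (all z equal) cannot be
fitted; it is flagged `degenerate`, reported at the initialization with
`fit_r2 = 0`, and excluded from downstream metrics.

The correlation-distance surface is often *flat in* $\sigma$ near its
minimum. Tests compare the optimizer against an exhaustive grid oracle
(integer-voxel centers, 0.25-voxel $\sigma$ steps): centers agree to one
grid step, and where the fitted $\sigma$ departs from the best grid
$\sigma$ the continuous optimum has a strictly lower objective than every
grid point — the grid, not the optimizer, is the coarser instrument there.

## Topography: rank linearity and its null

`rank_linearity()` measures whether neighboring seed voxels connect to
neighboring mapping locations. The three fitted center coordinates and the
three seed coordinates are each rank-transformed (average ranks for ties),
and the ranked centers are aligned to the ranked seed locations by the
least-squares similarity transform — translation, rotation and global
scale, *without* reflection, the literal reading of the transform set.
Linearity is the complement of the normalized Procrustes SSE, in $[0, 1]$.
Ranking makes the statistic invariant to any per-axis monotone distortion
of the fitted centers; the Procrustes step absorbs similarity transforms
*of the ranks*. (A rotation applied to raw centers does not commute with
ranking, so raw-space rotations change the value slightly — an inherent
property of any rank-based spatial statistic.)

Under no organization, the chance a voxel's data rank equals its spatial
rank is $1/V$, so the expected linearity of a $V$-voxel region is $1/V$;
spatial smoothness reduces the effective number of independent
observations to the resel count $V/\mathrm{FWHM}^3$, giving the corrected
expectation $1/(V/\mathrm{FWHM}^3)$, capped at 1. Inference treats
$\mathrm{round}(L \cdot V)$ as a binomial count with $V$ trials at that
success probability; results with $\le 10$ resels carry `low_resel_flag`,
because the binomial null is unreliable there.

Two calibration facts, both recomputed by `linearity_null_simulation()`
in the test suite and the acceptance script:

* at FWHM 1 (white fields) the permutation-null mean falls inside the
  binomial 95% interval around $1/V$ and the binomial test rejects about
  5% of null replicates;
* under genuinely *smoothed* null fields the measured mean linearity
  exceeds $1/\mathrm{resels}$ by a factor of roughly 3-4. The optimal 3-D
  rotation-plus-scale finds transient alignments between smooth random
  fields and the coordinate frame beyond what independence counting
  predicts, so the resel-corrected binomial should be read as a
  *first-order* null — anticonservative on smooth data — and the package
  reports the measured ratio rather than hiding it. The resel flag, not
  the binomial p alone, should gate inference on heavily smoothed regions.

The FWHM itself comes from `estimate_fwhm()`: a random-field-theory
estimator using the variance of spatial first differences of per-timepoint
standardized images, averaged over in-mask neighbor pairs, geometric-mean
across axes. White noise yields its intrinsic lattice smoothness
(about 1.18 voxels); a known smoothing kernel is recovered within a few
percent.

## Convergence: corrected 3-D KS

`convergence()` quantifies the opposite motif — many seed voxels
connecting to one place — as the deviance of the fitted centers from a
uniform distribution over the mapping region's voxel set, using a
Peacock-style 3-D Kolmogorov-Smirnov statistic (maximum
empirical-minus-reference cumulative difference over the eight orthant
orderings, anchored at the sample points). The reference is the *discrete
in-mask voxel set*, not the bounding box, so irregular region shapes do
not inflate the deviance. Because the raw statistic depends on sample size
and region geometry, it is divided by its Monte Carlo 5% critical value
(95th percentile over `n_null` uniform draws of equal size); values above
1 are significantly convergent at $\alpha = 0.05$, and by construction
uniform samples stay at or below 1 about 95% of the time. The ratio form
(rather than subtraction) keeps the quantity scale-free across regions.

## Vector fields

`vector_field()` draws, at each seed voxel, the vector from the mapping
region's center of mass to that voxel's fitted center. Topographic maps
show smoothly rotating vector patterns; convergent maps show all vectors
pointing to one spot. The norms color the default plot.

## Parcel-level machinery

`pairwise_linearity()` runs the fit and the linearity statistic over every
ordered parcel pair of a labeled volume. The matrix is *directed* — seeding
A into B is not the same model as seeding B into A — and is symmetrized
(mean of the two directions) only where a method needs a distance:

* `topography_graph()` draws an undirected edge when either direction
  exceeds the threshold (default 20%), sizes nodes by degree, and lays
  them out by classical MDS;
* `gradient_decomposition()` embeds parcels by nonmetric MDS
  (Kruskal stress, monotone regression) on $1 - \mathrm{linearity}$,
  with the classical solution, the previous dimensionality's warm start,
  and random configurations as restarts, keeping the best stress. The fit
  curve is the Spearman correlation between embedded and observed
  distances per candidate mode count; the mode count is chosen at the
  elbow — the most negative discrete second difference — and can be
  overridden. On a matrix built from exact 2-D latent coordinates the
  elbow selects 2.

`network_contrast()` compares each network's mean within-network linearity
against its mean linearity to other parcels, per subject, with a paired t
test across subjects. `task_map_regression()` is ordinary least squares of
a per-parcel task contrast on the gradients and the per-parcel average
convergence, all variables z-scored within the analyzed parcel set — hence
a zero intercept and standardized betas.

## The phantom generator

`generate_phantom()` builds the synthetic study conditions every statistic
is validated on. Mapping voxels carry independent Gaussian time series
(optionally smoothed to a stated FWHM); each seed voxel's series is the
Gaussian-weighted sum of mapping series under a known true field, scaled
to unit variance, plus white noise with variance $1/\mathrm{SNR}$. Three
schemes: `topographic` (an affine seed-to-mapping map, identity when the
shapes match), `convergent` (one locus), `null` (random centers). Defaults
are fixed once: 818 frames (a long single-session acquisition), SNR 2 (the
low end of the regime where half-voxel parameter recovery is expected),
$\sigma^\ast = 2$ voxels; validation runs state their sizes explicitly —
e.g. 200 recovery voxels at 300 frames, $\sigma^\ast \in \{1,2,3,4\}$, and
a $9^3$ (729-voxel) region with 1000 replicates for the null calibration,
the simulation sizes used throughout the tests and the acceptance script.

What the phantoms deliberately omit: hemodynamics, physiological and
motion artifacts, spatial nonstationarity, and anatomical geometry.
Passing these validations shows the estimator and its nulls behave as
designed under the generative model they assume — not that real cortical
connectivity satisfies that model.

## Numerical choices

* Correlations are Pearson, pairwise-complete over frames; censored (NaN)
  frames drop per voxel pair, with counts logged by the pipeline.
* $|r|$ is clamped at $1 - 10^{-7}$ before `atanh`; zero-variance series
  correlate as 0, with a warning.
* Rank ties take average ranks. All-identical fitted centers make the
  Procrustes scale degenerate; linearity is then 0, with a warning.
* Mask voxel order is fixed (z slowest, x fastest), so every matrix is
  reproducible across runs and platforms.
* The elbow needs at least three fit-curve points; with fewer, mode count
  defaults to the better of 1 and 2.
* Multiple-testing across many parcel pairs is left to the user's chosen
  procedure; p values are reported raw in the matrices (Bonferroni across
  mapping parcels is the convention used in the whole-brain literature).

## Limitations

* Single-Gaussian fields only: multi-focal connectivity is summarized by
  one blob (mixtures are a natural extension, not implemented).
* The binomial/resel null is anticonservative on smooth fields (measured
  factor 3-4 at FWHM 1.5-2); treat low-resel or heavily smoothed regions
  with the flag, or calibrate by Monte Carlo with
  `linearity_null_simulation()`.
* Volumetric only: cortical folding bends genuinely 2-D sheet topography
  through 3-D space, which depresses linearity for regions spanning sulci.
* Directed linearity matrices are symmetrized for MDS and graphs; the two
  directions genuinely differ and are preserved in the stored matrix.
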