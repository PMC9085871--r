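---
title: "Methods: structure-function coupling, heritability and gradients in couplemap"
author: "couplemap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-function coupling, heritability and gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplemap)
```

# What the package computes

`couplemap` studies how closely a cortical parcel's pattern of
microstructural similarity matches its pattern of intrinsic functional
connectivity, and how heritable both patterns are. Its pipeline has five
stages, each usable on its own:

1. **Equivolumetric depth sampling.** Intracortical surfaces are placed so
   that a fixed fraction $\alpha$ of local cortical volume lies above each
   surface. With local inner/outer surface areas $A_{in}$, $A_{out}$,
   $$\rho = \frac{-A_{in} + \sqrt{\alpha A_{out}^2 + (1-\alpha)A_{in}^2}}
   {A_{out}-A_{in}},$$
   continuous at $A_{in}=A_{out}$ where $\rho=\alpha$. Intensities sampled
   at these depths, averaged within parcels, give a parcels $\times$ depths
   profile matrix per subject (12 surfaces for human-like runs, 9 for
   macaque-like runs).

2. **Connectomes.** Microstructure profile covariance (MPC) between parcels
   $i$ and $j$ is the partial correlation of their depth profiles
   controlling for the cortex-wide mean profile $c$:
   $$\mathrm{MPC}(i,j) = \frac{r_{ij} - r_{ic}r_{jc}}
   {\sqrt{(1-r_{ic}^2)(1-r_{jc}^2)}},$$
   averaged over subjects. Functional connectivity is the Fisher-z
   transformed Pearson correlation of parcel timeseries, averaged over
   subjects on the z scale.

3. **Coupling.** Per parcel, the Spearman correlation between that parcel's
   MPC row and FC row (diagonal excluded), summarized per
   cytoarchitectural class (idiotypic, unimodal, heteromodal, paralimbic)
   and contrasted between classes by Welch t-tests with Bonferroni
   correction over the four classes.

4. **Heritability.** An AE (additive genetic + unique environment) twin
   model fitted by maximum likelihood:
   $y \sim N(X\beta,\ \sigma^2_g K + \sigma^2_e I)$ with kinship $K$ equal
   to the genetic correlation (1 in MZ pairs, 0.5 in DZ pairs), and
   $h^2 = \sigma^2_g/\sigma^2_p$. Phenotypes are inverse-normal transformed;
   covariates (intercept, centered age, sex, age$^2$, age$\times$sex) are
   estimated jointly inside the fit.

5. **Gradients, nulls and decoding.** Diffusion-map embedding of
   row-thresholded, angle-kernel affinities; Procrustes alignment between
   modalities; the difference map $\Delta = z(\mathrm{FC\,G1}) -
   z(\mathrm{MPC\,G1})$; spherical spin-test permutation nulls; and the
   2D quadrant model (difference on x, coupling on y) with quadrant
   $\chi^2$ comparisons and 20-bin weighted term ranking.

# The synthetic-data generator

Real analyses of this kind need large restricted imaging cohorts. The
generator produces small cortices whose ground truth is known, so every
stage can be verified end to end.

**Geometry.** `makeToyCortex()` spreads parcels over the unit sphere with a
Fibonacci lattice, splits hemispheres at $x = 0$, assigns one quarter of
parcels per class in contiguous lattice blocks (classes are spatially
coherent, as in real cortex), and draws per-vertex inner/outer areas with
outer > inner, a gyral-crown-like default.

**Microstructure.** Each class has a quadratic mean profile over depth
$d \in [0,1]$: intensity $= a + bd + cd^2$. Defaults run from a high,
steeply declining idiotypic profile (heavy myelination) to a low, flat
paralimbic one. Two stable random depth signatures are layered on top: a
class-level signature (`classEffectSd = 0.08`) shared by all parcels of a
class, which makes within-class profiles reliably more alike than
between-class ones, and a parcel-level signature (`parcelEffectSd = 0.15`)
that gives the within-class similarity a graded pattern. Subjects add a
random intercept/slope shift (`subjectNoiseSd = 0.02`) and vertices add
iid measurement noise (`vertexNoiseSd = 0.05`).

The generator's ground-truth similarity is the *partial* correlation of
the noiseless parcel profiles given the cortex-wide mean profile
(`populationSimilarity()`), i.e., exactly the population quantity the MPC
estimator targets. Raw profile correlations are unsuitable as ground
truth: every profile declines with depth, so raw correlations are all
close to one and nearly rank-one.

**Function.** Timeseries are multivariate normal with a correlation target
built per class block as the convex blend
$\kappa_c S + (1-\kappa_c)\,C$, where $S$ is the microstructural
similarity and $C$ an independent two-community structure within the
class; across classes the correlation is $\kappa_i \kappa_j S_{ij}$. The
product damping matters: a Spearman coupling is invariant to monotone
rescaling of a row, so class coupling cannot be encoded as row amplitude.
What erodes coupling for a low-$\kappa$ class is that its
microstructure-linked covariance falls below the finite-scan sampling
noise of the correlation estimate (T = 600 timepoints, measurement noise
sd 0.2 by default). Non-positive-definite blends are repaired by minimal
diagonal loading, reported via `message()`. The default coupling targets
$\kappa$ = (0.9, 0.5, 0.1, 0.1) for (idiotypic, unimodal, heteromodal,
paralimbic) mirror the strong-to-absent structure-function coupling
gradient the analysis is designed to detect.

**Twins.** `simulateTwinCohort()` draws phenotypes directly on the scale
of the AE model: $y = X\beta + g + e$ with total variance 1,
$\mathrm{Var}(g) = h^2$, genetic correlation 1 / 0.5 / 0 within MZ / DZ /
unrelated pairs. Twins share their family's age (uniform 22-36 years,
young-adult-cohort-like); sex is balanced. Default covariate effects are
small but non-zero, so covariate absorption is exercised. Generating on
the model's own scale isolates estimator correctness from transform
artifacts; the inverse normal transform applied by `mapHeritability()`
then makes the fit invariant to any monotone rescaling of real inputs.

All randomness flows from one master seed through named substreams
(`withSubstream()`), so each stage is reproducible in isolation and the
profile and timeseries stages agree on the same ground-truth similarity.

# Numerical and design choices

* **Depth grid.** $\alpha_k = k/(n+1)$, $k = 1..n$: surfaces strictly
  between the pial and white boundaries, avoiding boundary partial-volume
  samples. The equal-area limit of the equivolumetric formula is switched
  in when $|A_{out}-A_{in}| < 10^{-9}A_{in}$.
* **Diagonals** of both connectome kinds are set to 0 and excluded from
  all row-wise statistics; self-similarity is uninformative.
* **Clipping.** Correlations are clipped to $\pm(1-10^{-7})$ before
  `atanh`, keeping noiseless synthetic data finite. Negative MPC values
  are retained; `threshold = TRUE` reproduces the zero-thresholded variant
  of the older MPC literature.
* **Row thresholding** keeps entries at or above the row's 90th
  percentile. Ties at the threshold all survive, so an all-equal row
  survives whole.
* **Diffusion maps** use $\alpha = 0.5$ and multiscale scaling
  $\lambda/(1-\lambda)$ for $t = 0$ (the convention of the standard
  gradient-mapping toolchain; `multiscale = FALSE` gives the literal
  $\lambda^0$). Component signs are fixed by making each component's
  largest-magnitude entry positive. Disconnected affinities are embedded
  on the largest connected component with the rest flagged missing, since
  global eigenvectors of a disconnected operator are not interpretable.
* **AE optimization** profiles $\beta$ and $\sigma^2_p$ out analytically
  per candidate $h^2$ (2 $\times$ 2 family blocks inverted in closed
  form), then maximizes over logit($h^2$) from multiple starts (0.1, 0.5,
  0.9) with explicit boundary evaluation; ties resolve to the highest
  log-likelihood, then the smallest $h^2$. The LRT against
  $\sigma^2_g = 0$ uses the boundary mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Standard errors come from the
  numerical observed information of the profile likelihood (undefined at
  the boundary, reported as `NA`).
* **Procrustes** alignment is a pure rotation (SVD of the cross-product,
  no scaling); the FC gradients are the default reference. The
  $\Delta$ map orientation is fixed, when an atlas is supplied, by
  sign-orienting both principal gradients so the idiotypic-class mean is
  negative before subtraction.
* **Spin nulls** operate at parcel level: a uniform random rotation of the
  left-hemisphere centroids (x-mirrored for the right hemisphere) followed
  by greedy nearest-first one-to-one reassignment. Greedy matching avoids
  duplicate assignments that would shrink map variance. P-values use the
  $(1+k)/(1+n_{perm})$ convention and are two-sided.
* **Term decoding** shifts each term's bin means to be non-negative before
  the weighted average (a weighted mean is undefined for negative
  z-scores); `shift = FALSE` gives the unshifted variant. Bins are
  rank-based with ties broken by parcel index; term rank ties break by
  term name.
* **Welch** (unequal-variance) t-tests are used for class contrasts;
  class sizes and variances differ in practice.

# What the tests do and do not show

The test suite verifies the estimators against independent oracles
(residualized partial correlation for MPC, dense eigendecomposition for
the diffusion map, dense-matrix grid search for the AE likelihood, Welch
and Pearson formulas for the contrasts), checks distributional
calibration (AE LRT type-I error within [0.03, 0.07] at nominal 0.05 over
1000 null cohorts of 500 MZ + 500 DZ pairs; spin-test rejection within
[0.03, 0.07] over 200 simulations of independent smooth maps at 100
rotations each), and confirms end-to-end recovery of the generative class
coupling ordering in at least 19 of 20 seeded runs (80 parcels, 10
subjects per run — sizes chosen to keep the default suite fast while
leaving comfortable statistical margins).

The generator emulates the statistical structure the analysis assumes —
class-structured depth profiles, community-structured BOLD-like
covariance, additive-genetic family covariance — not the physics of
imaging. It has no hemodynamics, motion, surface geometry beyond local
areas, or non-additive genetics; passing tests demonstrate correctness of
the estimators and pipeline logic under the stated model, not robustness
to real-data artifacts.

Known limitations worth stating plainly:

* The parcel-level spin test, like parcel-level spins generally, grows
  anticonservative in the limit of extremely smooth maps with only a few
  effective degrees of freedom (e.g., pure low-order spherical
  harmonics); calibration was verified for Gaussian-process maps with
  geodesic correlation lengths of roughly 0.2-0.3 radians, the regime of
  typical cortical maps; at 0.5 radians and beyond (very few effective
  degrees of freedom over 100 parcels) mild anticonservatism appears.
* A rank correlation against a *binary* indicator cannot exceed
  $\sqrt{3}/2 \approx 0.87$; community-separation checks therefore use the
  point-biserial (Pearson) correlation.
* With distinct class mean curves, block-level class structure leaves a
  small residual structure-function association even at $\kappa = 0$; the
  zero-coupling limit is exact only when class profiles are exchangeable
  (identical curves, no class signature), and is tested in that regime.
* ML (not REML) variance estimates are used, as in the profile-likelihood
  tradition of the quantitative-genetics toolchain being emulated; with
  covariate counts tiny relative to cohort sizes the bias is negligible
  for $h^2$.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates all headline
quantities from scratch: class-mean coupling under the default $\kappa$,
the idiotypic-vs-heteromodal contrast, mean recovered $h^2$ on a
991-subject study-sized cohort generated at $h^2 = 0.5$, the
gradient-difference null, spin-test calibration, and the quadrant
$\chi^2$ between a default and a strongly-coupled (macaque-like)
condition.
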