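# couplemap

Tools for studying **structure–function coupling** in the cerebral cortex:
how closely a cortical parcel's pattern of microstructural similarity
matches its pattern of intrinsic functional connectivity, how heritable
both patterns are, and how their large-scale organizational gradients
diverge.

The package is aimed at researchers in network neuroscience and imaging
genetics who work with parcellated cortical data — depth-wise myelin-
sensitive intensity profiles, resting-state timeseries, and twin
pedigrees — and at anyone who wants a fully testable, self-contained
implementation of this analysis family. Because the real cohorts such
analyses need are large and access-restricted, `couplemap` ships a
synthetic-cohort generator with known ground truth, so the entire pipeline
runs and can be validated on a laptop.

## The core quantities

* **Equivolumetric depth sampling.** An intracortical surface holding a
  fraction α of the local cortical volume above it sits at depth
  ρ = (−A<sub>in</sub> + √(αA<sub>out</sub>² + (1−α)A<sub>in</sub>²)) /
  (A<sub>out</sub> − A<sub>in</sub>), correcting depth for cortical folding
  (ρ = α where the areas are equal).
* **Microstructure profile covariance (MPC).** For parcels i, j with depth
  profiles correlated r<sub>ij</sub>, and r<sub>ic</sub>, r<sub>jc</sub>
  their correlations with the cortex-wide mean profile c,
  MPC(i,j) = (r<sub>ij</sub> − r<sub>ic</sub>r<sub>jc</sub>) /
  √((1−r<sub>ic</sub>²)(1−r<sub>jc</sub>²)), averaged over subjects.
* **rsFC.** Fisher-z transformed Pearson correlation of parcel timeseries.
* **Coupling.** Per parcel, Spearman's ρ between its MPC row and rsFC row,
  summarized over the four cytoarchitectural classes (idiotypic, unimodal,
  heteromodal, paralimbic) with Welch contrasts, Bonferroni-corrected by 4.
* **Heritability.** Twin-based AE maximum-likelihood variance
  decomposition, h² = σ²g/σ²p, with inverse-normal transformed phenotypes,
  joint covariate estimation (age, sex, age², age×sex) and a boundary-
  mixture likelihood-ratio test.
* **Gradients.** Diffusion-map embeddings (top-10% row threshold,
  normalized-angle kernel, α = 0.5, multiscale t = 0) with Procrustes
  alignment, the gradient-difference map Δ = z(FC G1) − z(MPC G1),
  spherical spin-test nulls, and a 2D quadrant/term-decoding model.

## Worked example

Simulate a cohort whose generative class coupling is
κ = (0.9, 0.5, 0.1, 0.1) and recover the coupling ordering:

```r
library(couplemap)

res <- runCouplingPipeline(nParcels = 80, nSubjects = 10, seed = 1)
res$mpc
#> ConnectivityMatrix [MPC] 80 x 80, subject: group-mean
res$classSummary
#>        class  n      mean         sd
#>    idiotypic 20 0.9025110 0.02518821
#>     unimodal 20 0.8027836 0.06648483
#>  heteromodal 20 0.6758179 0.09157900
#>   paralimbic 20 0.6843208 0.09590126

ct <- classContrast(res$coupling, res$cortex@atlas, "idiotypic", "heteromodal")
sprintf("t = %.2f, corrected p = %.3g", ct$t, ct$pCorrected)
#> "t = 10.67, corrected p = 1.56e-09"
```

The class-mean coupling falls from idiotypic (0.90) through unimodal
(0.80) to the two transmodal classes (≈0.68), recovering the generative
ordering; the idiotypic-vs-heteromodal Welch contrast is decisive.

Heritability of a phenotype simulated at h² = 0.5 on a 991-subject twin
cohort (127 MZ pairs, 75 DZ pairs, 587 singletons):

```r
co  <- simulateTwinCohort(127, 75, 587, h2True = 0.5, seed = 2)
est <- fitAE(inverseNormalTransform(phenotypes(co)[, 1]), co)
est
#> AE heritability: h2 = 0.537 (SE 0.058), sigma2g = 0.511, sigma2e = 0.440
#>   loglik = -1356.821, LRT p = 1.882e-11
```

The estimate (0.537 ± 0.058) covers the generating value 0.5, and the
likelihood-ratio test firmly rejects the environment-only model.

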