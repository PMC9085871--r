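test_that("toy cortex construction is balanced, unit-norm and deterministic", {
  cx <- makeToyCortex(8, seed = 1)
  expect_s4_class(cx, "ToyCortex")
  expect_equal(as.numeric(table(classLabels(cx@atlas))), rep(2L, 4L))
  expect_true(all(abs(sqrt(rowSums(centroids(cx@atlas)^2)) - 1) < 1e-9))
  cx2 <- makeToyCortex(8, seed = 1)
  expect_identical(cx@innerArea, cx2@innerArea)
  expect_identical(centroids(cx@atlas), centroids(cx2@atlas))
  expect_error(makeToyCortex(4, seed = 1), "divisible")
  expect_error(makeToyCortex(10, seed = 1), "divisible")

  big <- makeToyCortex(400, seed = 7)
  expect_equal(as.numeric(table(classLabels(big@atlas))), rep(100L, 4L))
  expect_true(all(big@outerArea > big@innerArea))
  expect_true(all(table(hemispheres(big@atlas)) >= 150))
})

test_that("zero-noise profiles collapse to the class curve", {
  cx <- makeToyCortex(8, seed = 3, verticesPerParcel = 4L)
  # equal areas force identical equivolumetric depths across vertices
  flat <- new("ToyCortex", atlas = cx@atlas, vertexParcel = cx@vertexParcel,
              innerArea = rep(1, length(cx@innerArea)),
              outerArea = rep(1, length(cx@outerArea)))
  spec <- generativeSpec(vertexNoiseSd = 0, subjectNoiseSd = 0,
                         parcelEffectSd = 0, seed = 3)
  sim <- simulateDepthProfiles(flat, spec, 2)
  cls <- as.integer(classLabels(cx@atlas))[flat@vertexParcel]
  for (cl in unique(cls)) {
    rows <- sim$profiles[cls == cl, , 1]
    expect_true(max(abs(sweep(rows, 2, rows[1, ]))) < 1e-12)
  }
})

test_that("within-class profiles are more alike than between-class ones", {
  diffs <- vapply(1:20, function(s) {
    cx <- makeToyCortex(16, seed = s, verticesPerParcel = 4L)
    spec <- generativeSpec(seed = s)
    pm <- parcelMeanProfiles(simulateDepthProfiles(cx, spec, 1)$profiles[, , 1],
                             cx@vertexParcel, 16)
    cc <- cor(t(pm))
    cls <- as.character(classLabels(cx@atlas))
    same <- outer(cls, cls, "==") & upper.tri(cc)
    diff <- !outer(cls, cls, "==") & upper.tri(cc)
    mean(cc[same]) - mean(cc[diff])
  }, numeric(1))
  # all class curves decline with depth, so raw profile correlations are
  # high everywhere; the within-class advantage holds in expectation
  expect_gt(mean(diffs), 0)
  expect_gte(mean(diffs > 0), 0.75)

  # symmetry: identical curve parameters abolish the class gap
  curves <- matrix(rep(c(1.3, -0.5, 0.1), each = 4), 4, 3,
                   dimnames = list(c("idiotypic", "unimodal", "heteromodal",
                                     "paralimbic"), NULL))
  gaps <- vapply(1:20, function(s) {
    cx <- makeToyCortex(16, seed = s, verticesPerParcel = 4L)
    S <- populationSimilarity(cx, generativeSpec(seed = s, classCurves = curves,
                                                 classEffectSd = 0))
    cls <- as.character(classLabels(cx@atlas))
    same <- outer(cls, cls, "==") & upper.tri(S)
    diff <- !outer(cls, cls, "==") & upper.tri(S)
    mean(S[same]) - mean(S[diff])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.05)
})

test_that("full coupling blend reproduces the similarity and vanishes at kappa zero", {
  cx <- makeToyCortex(24, seed = 5, verticesPerParcel = 4L)
  spec <- generativeSpec(seed = 5, tsLength = 3000L, tsNoiseSd = 0.01,
                         kappa = c(idiotypic = 1, unimodal = 1,
                                   heteromodal = 1, paralimbic = 1))
  S <- populationSimilarity(cx, spec)
  ts <- suppressMessages(simulateTimeseries(cx, spec, 1))
  fc <- cor(ts[[1]])
  expect_gt(cor(S[upper.tri(S)], fc[upper.tri(fc)]), 0.95)

  # kappa = 0 with identical class curves: no structure-function overlap
  curves <- matrix(rep(c(1.3, -0.5, 0.1), each = 4), 4, 3)
  rownames(curves) <- c("idiotypic", "unimodal", "heteromodal", "paralimbic")
  ms <- vapply(1:5, function(s) {
    sp <- generativeSpec(seed = s, classCurves = curves, classEffectSd = 0,
                         kappa = c(idiotypic = 0, unimodal = 0,
                                   heteromodal = 0, paralimbic = 0))
    res <- suppressMessages(runCouplingPipeline(48, 8, seed = s, spec = sp))
    mean(res$coupling)
  }, numeric(1))
  expect_lt(abs(mean(ms)), 0.1)
})

test_that("blend covariance is symmetric positive semi-definite", {
  for (s in 1:5) {
    cx <- makeToyCortex(20, seed = s, verticesPerParcel = 3L)
    sigma <- suppressMessages(
      couplemap:::blendedCovariance(cx, generativeSpec(seed = s)))
    expect_equal(sigma, t(sigma))
    expect_gt(min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("twin cohorts realize the AE covariance structure", {
  pairCor <- function(co, zyg) {
    ped <- pedigree(co); y <- phenotypes(co)[, 1]
    i <- which(ped$zygosity == zyg)
    i1 <- i[seq(1, length(i), by = 2)]
    cor(y[i1], y[i1 + 1L])
  }
  # no genetic variance: both pair correlations near zero
  co0 <- simulateTwinCohort(300, 300, 0, 0, covariateBetas = rep(0, 5), seed = 2)
  expect_lt(abs(pairCor(co0, "MZ")), 0.12)
  expect_lt(abs(pairCor(co0, "DZ")), 0.12)
  # full heritability, no covariates: MZ correlation exactly 1
  co1 <- simulateTwinCohort(50, 50, 0, 1, covariateBetas = rep(0, 5), seed = 3)
  expect_equal(pairCor(co1, "MZ"), 1)
  expect_gt(pairCor(co1, "DZ"), 0.2)
  # intermediate: r_MZ ~ h2, r_DZ ~ h2/2
  co5 <- simulateTwinCohort(500, 500, 0, 0.5, covariateBetas = rep(0, 5), seed = 4)
  expect_lt(abs(pairCor(co5, "MZ") - 0.5), 0.08)
  expect_lt(abs(pairCor(co5, "DZ") - 0.25), 0.1)
  expect_error(simulateTwinCohort(10, 10, 0, 1.2, seed = 1), "\\[0, 1\\]")

  # falconer moment check: mean 2 (r_MZ - r_DZ) recovers h2
  h2 <- 0.4
  fal <- vapply(1:200, function(r) {
    co <- simulateTwinCohort(150, 150, 0, h2, covariateBetas = rep(0, 5),
                             seed = 100 + r)
    2 * (pairCor(co, "MZ") - pairCor(co, "DZ"))
  }, numeric(1))
  expect_lt(abs(mean(fal) - h2), 0.05)
})

test_that("cohort structure and determinism contracts hold", {
  co <- simulateTwinCohort(5, 4, 3, 0.5, seed = 9)
  ped <- pedigree(co)
  expect_equal(nrow(ped), 21L)
  expect_true(all(table(ped$family_id[ped$zygosity != "singleton"]) == 2L))
  # twins share their family age
  for (f in unique(ped$family_id[ped$zygosity == "MZ"]))
    expect_equal(diff(ped$age[ped$family_id == f]), 0)
  co2 <- simulateTwinCohort(5, 4, 3, 0.5, seed = 9)
  expect_identical(phenotypes(co), phenotypes(co2))
  expect_identical(ped, pedigree(co2))
  # spec validation
  expect_error(generativeSpec(vertexNoiseSd = -1), "non-negative")
  expect_error(generativeSpec(kappa = c(idiotypic = 2, unimodal = 0.5,
                                        heteromodal = 0.1, paralimbic = 0.1)))
  expect_error(generativeSpec(nDepths = 1))
})
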