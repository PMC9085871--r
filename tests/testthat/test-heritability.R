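test_that("inverse normal transform maps ranks to normal quantiles", {
  expect_equal(inverseNormalTransform(c(3, 1, 2)),
               qnorm(c(0.75, 0.25, 0.5)), tolerance = 1e-12)
  expect_equal(inverseNormalTransform(c(3, 1, 2))[3], 0)
  # rank invariance under monotone rescaling
  set.seed(1)
  x <- rnorm(50)
  expect_equal(inverseNormalTransform(x), inverseNormalTransform(exp(x)))
  # large-sample moments
  set.seed(2)
  u <- runif(1001)
  ti <- inverseNormalTransform(u)
  expect_lt(abs(mean(ti)), 0.05)
  expect_equal(sd(ti), 1, tolerance = 0.05)
  expect_warning(out <- inverseNormalTransform(rep(2, 5)), "identical")
  expect_equal(out, rep(0, 5))
  expect_error(inverseNormalTransform(c(1, 2)), "3 finite")
})

test_that("design matrix has the covariate structure of the model", {
  X <- buildDesignMatrix(c(20, 30), c(0, 1))
  expect_equal(unname(X),
               rbind(c(1, -5, 0, 25, 0), c(1, 5, 1, 25, 5)))
  co <- simulateTwinCohort(5, 5, 3, 0.5, seed = 1)
  expect_equal(ncol(buildDesign(co)), 5L)
  # degenerate design (all ages equal) still yields a fit via pseudo-inverse
  ped <- pedigree(co); ped$age <- rep(30, nrow(ped))
  co2 <- new("TwinCohort", pedigree = ped, phenotypes = phenotypes(co))
  est <- fitAE(phenotypes(co2)[, 1], co2)
  expect_true(is.finite(est@loglik))
})

test_that("maximized likelihood matches a dense brute-force oracle", {
  for (s in 1:3) {
    co <- simulateTwinCohort(15, 15, 10, 0.6, seed = 20 + s)
    y <- inverseNormalTransform(phenotypes(co)[, 1])
    est <- fitAE(y, co)
    Xd <- buildDesign(co)
    grid <- seq(0, 0.999, by = 0.002)
    oracle <- max(vapply(grid, function(h)
      denseAeLoglik(h, y, Xd, pedigree(co)), numeric(1)))
    expect_equal(est@loglik, oracle, tolerance = 1e-4)
    expect_gte(est@loglik, oracle - 1e-6)
    # h2 identity
    expect_equal(est@h2, est@sigma2g / est@sigma2p, tolerance = 1e-9)
  }
})

test_that("AE fit recovers boundary and intermediate heritabilities", {
  # perfect heritability: MZ identical, DZ correlated 0.5, no noise
  co1 <- simulateTwinCohort(60, 60, 0, 1, covariateBetas = rep(0, 5), seed = 5)
  est1 <- fitAE(phenotypes(co1)[, 1], co1)
  expect_gt(est1@h2, 0.98)
  expect_lt(est1@p, 1e-6)
  # family-independent phenotype: h2 near zero
  co0 <- simulateTwinCohort(200, 200, 50, 0, covariateBetas = rep(0, 5), seed = 6)
  est0 <- fitAE(phenotypes(co0)[, 1], co0)
  expect_lt(est0@h2, 0.12)
  # parameter recovery at h2 = 0.5 over replicates
  ests <- vapply(1:30, function(r) {
    co <- simulateTwinCohort(300, 300, 0, 0.5, seed = 30 + r)
    fitAE(inverseNormalTransform(phenotypes(co)[, 1]), co)@h2
  }, numeric(1))
  expect_equal(mean(ests), 0.5, tolerance = 0.05)
  # scale equivariance: shifting or rescaling leaves h2 unchanged
  co <- simulateTwinCohort(100, 100, 0, 0.4, seed = 77)
  y <- phenotypes(co)[, 1]
  expect_equal(fitAE(y, co)@h2, fitAE(5 + 3 * y, co)@h2, tolerance = 1e-6)
  # singletons alone are unidentifiable
  cos <- simulateTwinCohort(0, 0, 30, 0.5, seed = 8)
  expect_error(fitAE(phenotypes(cos)[, 1], cos), "unidentifiable")
})

test_that("null LRT p-values are conservative-to-nominal under h2 = 0", {
  ps <- vapply(1:100, function(r) {
    co <- simulateTwinCohort(150, 150, 0, 0, seed = 500 + r)
    fitAE(inverseNormalTransform(phenotypes(co)[, 1]), co)@p
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0.0)
  expect_lte(mean(ps <= 0.05), 0.12)
  expect_gt(mean(ps > 0.5), 0.3)     # boundary mass at p = 1
})

test_that("heritability maps run phenotype-wise and flag failures", {
  co <- simulateTwinCohort(150, 150, 20, c(0.6, 0.6, 0), seed = 11)
  ph <- phenotypes(co)
  ph <- cbind(ph, ph[, 1], broken = rep(1, nrow(ph)))
  colnames(ph) <- c("a", "b", "null", "a_copy", "broken")
  res <- mapHeritability(ph, co)
  expect_equal(nrow(res), 5L)
  expect_equal(res$h2[res$phenotype == "a"],
               res$h2[res$phenotype == "a_copy"])
  expect_true(is.na(res$h2[res$phenotype == "broken"]))
  expect_gt(res$h2[res$phenotype == "a"], res$h2[res$phenotype == "null"])
  # covariate absorption: pure covariate signal is not called heritable
  X <- buildDesign(co)
  set.seed(12)
  fake <- as.numeric(X %*% c(0, 0.5, 1, 0.05, 0.1)) + rnorm(nrow(X))
  est <- fitAE(inverseNormalTransform(fake), co)
  expect_lt(est@h2, 0.12)
})

test_that("edge phenotype stacking and reshaping are inverse operations", {
  mats <- lapply(1:3, function(s) randomConnectivity(5, s))
  ph <- connectivityPhenotypes(mats)
  expect_equal(dim(ph), c(3L, 10L))
  back <- edgeValuesToMatrix(ph[2, ], parcelIds(mats[[2]]))
  expect_equal(unname(back), mats[[2]]@mat, tolerance = 1e-12)
})
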