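test_that("row thresholding keeps the top percentile with tie survival", {
  set.seed(1)
  m <- matrix(rnorm(100), 10, 10)
  thr <- thresholdRows(m, 90)
  for (i in 1:10) {
    expect_equal(sum(thr[i, ] != 0), 1L)          # 10 columns at 90%: the max
    expect_equal(which(thr[i, ] != 0), which.max(m[i, ]))
  }
  # all-equal row: every entry ties at the percentile and survives
  m2 <- m; m2[3, ] <- 2
  expect_equal(thresholdRows(m2, 90)[3, ], rep(2, 10))
  # random case against a sort-per-row oracle
  set.seed(2)
  m3 <- matrix(rnorm(400), 20, 20)
  got <- thresholdRows(m3, 80)
  for (i in 1:20) {
    cut <- quantile(m3[i, ], 0.8, type = 7)
    keep <- sort(m3[i, m3[i, ] >= cut], decreasing = TRUE)
    expect_equal(sort(got[i, got[i, ] != 0], decreasing = TRUE), keep)
  }
  expect_error(thresholdRows(m3, 0), "pct")
  expect_error(thresholdRows(m3, 100), "pct")
  expect_error(thresholdRows(matrix(0, 2, 3), 90), "square")
})

test_that("normalized-angle kernel maps angles onto [0, 1]", {
  m <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 2, 0), c(-3, 0, 0))
  aff <- normalizedAngleAffinity(m)
  expect_equal(aff[1, 2], 1)       # identical direction
  expect_equal(aff[1, 3], 0.5)     # orthogonal
  expect_equal(aff[1, 4], 0)       # anti-parallel
  expect_identical(aff, t(aff))
  expect_true(all(aff >= 0 & aff <= 1))
  expect_error(normalizedAngleAffinity(rbind(c(1, 1), c(0, 0))), "zero row")
})

test_that("diffusion embedding matches a dense Markov eigendecomposition", {
  for (s in 1:5) {
    set.seed(s)
    n <- 50
    base <- matrix(runif(n * n), n, n)
    aff <- (base + t(base)) / 2 + diag(n)     # symmetric, positive
    gs <- diffusionMap(aff, alpha = 0.5, t = 0, nComponents = 5)
    # oracle: plain (non-symmetric) eigendecomposition of the Markov operator
    d <- rowSums(aff)
    Wp <- aff / outer(d^0.5, d^0.5)
    P <- Wp / rowSums(Wp)
    eo <- eigen(P)
    ord <- order(-Re(eo$values))
    lamO <- Re(eo$values[ord])
    expect_equal(gs@eigenvalues, lamO[2:6], tolerance = 1e-8)
    for (k in 1:3) {
      v <- Re(eo$vectors[, ord[k + 1]])
      u <- gs@components[, k]
      # subspace angle between matched eigenvectors
      ang <- acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))))
      expect_lt(ang, 1e-6)
    }
  }
})

test_that("embedding respects permutation equivariance and orthogonality", {
  set.seed(9)
  n <- 30
  base <- matrix(runif(n * n), n, n)
  aff <- (base + t(base)) / 2 + diag(n)
  gs <- diffusionMap(aff, nComponents = 4)
  expect_true(all(diff(gs@eigenvalues) <= 1e-12))
  perm <- sample(n)
  gsp <- diffusionMap(aff[perm, perm], nComponents = 4)
  for (k in 1:4) {
    delta <- min(max(abs(gsp@components[, k] - gs@components[perm, k])),
                 max(abs(gsp@components[, k] + gs@components[perm, k])))
    expect_lt(delta, 1e-8)
  }
  # orthogonality under the stationary weight of the Markov chain
  d <- rowSums(aff)
  Wp <- aff / outer(d^0.5, d^0.5)
  pi0 <- rowSums(Wp) / sum(Wp)
  G <- gs@components
  gram <- t(G) %*% (pi0 * G)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
})

test_that("degenerate and disconnected affinities are handled explicitly", {
  # rank-one affinity: no non-trivial structure
  ones <- matrix(1, 12, 12)
  gs <- diffusionMap(ones, nComponents = 3)
  expect_lt(max(abs(gs@eigenvalues)), 1e-10)
  expect_lt(max(abs(gs@components)), 1e-8)
  # two weakly-bridged communities: principal component separates them
  blk <- matrix(0.05, 20, 20)
  blk[1:10, 1:10] <- 0.9; blk[11:20, 11:20] <- 0.9
  diag(blk) <- 1
  g1 <- diffusionMap(blk, nComponents = 2)@components[, 1]
  expect_true(all(sign(g1[1:10]) != sign(g1[11:20])))
  # fully disconnected blocks: largest component embedded, rest missing
  disc <- matrix(0, 15, 15)
  disc[1:9, 1:9] <- 0.8; disc[10:15, 10:15] <- 0.8
  diag(disc) <- 1
  expect_warning(gsd <- diffusionMap(disc, nComponents = 2), "disconnected")
  expect_true(all(is.na(gsd@components[10:15, ])))
  expect_true(all(is.finite(gsd@components[1:9, ])))
  expect_error(diffusionMap(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("principal gradient separates communities across the sweep grid", {
  set.seed(3)
  n <- 40
  sim <- matrix(0.1, n, n)
  sim[1:20, 1:20] <- 0.8; sim[21:40, 21:40] <- 0.8
  sim <- sim + matrix(rnorm(n * n, sd = 0.02), n, n)
  sim <- (sim + t(sim)) / 2; diag(sim) <- 1
  aff <- normalizedAngleAffinity(thresholdRows(sim, 75))
  indicator <- rep(c(1, 2), each = 20)
  for (alpha in seq(0, 1, by = 0.1)) for (tt in 0:9) {
    g1 <- diffusionMap(aff, alpha = alpha, t = tt,
                       nComponents = 2)@components[, 1]
    # point-biserial correlation with the binary community indicator
    # (a rank correlation against a binary vector caps at sqrt(3)/2)
    expect_gt(abs(cor(g1, indicator)), 0.9)
  }
})

test_that("Procrustes alignment recovers planted rotations exactly", {
  set.seed(6)
  comp <- matrix(rnorm(40 * 4), 40, 4)
  ref <- new("GradientSet", components = comp,
             eigenvalues = sort(runif(4), decreasing = TRUE), kind = "FC",
             alignment = "raw", parcelIds = sprintf("p%02d", 1:40))
  # identity case
  al0 <- procrustesAlign(ref, ref)
  expect_equal(al0@components, comp, tolerance = 1e-12)
  # planted rotation
  qr0 <- qr(matrix(rnorm(16), 4, 4))
  R <- qr.Q(qr0)
  src <- ref; src@components <- comp %*% R; src@kind <- "MPC"
  al <- procrustesAlign(src, ref)
  expect_lt(max(abs(al@components - comp)), 1e-10)
  expect_equal(al@alignment, "procrustes-to-FC")
  # sign flip of a single component is undone
  flip <- ref; flip@components[, 2] <- -comp[, 2]; flip@kind <- "MPC"
  alf <- procrustesAlign(flip, ref)
  expect_lt(max(abs(alf@components - comp)), 1e-10)
  # rank-deficient cross-product falls back to identity
  degen <- ref; degen@components <- matrix(0, 40, 4)
  expect_warning(ald <- procrustesAlign(degen, ref), "identity")
  expect_equal(ald@components, degen@components)
})

test_that("gradient differences are standardization-invariant", {
  set.seed(7)
  comp <- matrix(rnorm(24 * 2), 24, 2)
  g1 <- new("GradientSet", components = comp, eigenvalues = c(0.9, 0.5),
            kind = "MPC", alignment = "raw",
            parcelIds = sprintf("p%02d", 1:24))
  g2 <- g1; g2@kind <- "FC"
  expect_equal(unname(gradientDifference(g1, g2)), rep(0, 24))
  # affine rescaling vanishes after z-standardization
  g3 <- g2; g3@components <- 3 * comp + 5
  expect_equal(unname(gradientDifference(g1, g3)), rep(0, 24),
               tolerance = 1e-12)
  gz <- g2; gz@components[, 1] <- 1
  expect_error(gradientDifference(g1, gz), "zero-variance")
})

test_that("homolog gradient selection finds the matching component", {
  set.seed(8)
  comp <- matrix(rnorm(30 * 4), 30, 4)
  gs <- new("GradientSet", components = comp,
            eigenvalues = sort(runif(4), decreasing = TRUE), kind = "FC",
            alignment = "raw", parcelIds = sprintf("p%02d", 1:30))
  expect_equal(selectHomologGradient(gs, comp[, 3])$component, 3L)
  selNeg <- selectHomologGradient(gs, -comp[, 2])
  expect_equal(selNeg$component, 2L)
  expect_equal(selNeg$sign, -1)
  noisy <- comp[, 1] + rnorm(30, sd = 0.3 * sd(comp[, 1]))
  expect_equal(selectHomologGradient(gs, noisy)$component, 1L)
})
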