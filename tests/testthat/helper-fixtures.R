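# Shared fixture builders. Everything is generated in code at test time.

tinyCortex <- function(nParcels = 16L, seed = 1L, verticesPerParcel = 5L) {
  makeToyCortex(nParcels, seed = seed, verticesPerParcel = verticesPerParcel)
}

# symmetric random matrix with zero diagonal wrapped as a ConnectivityMatrix
randomConnectivity <- function(n, seed, kind = "FC_z") {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new("ConnectivityMatrix", mat = m, kind = kind, subject = "sim",
      parcelIds = sprintf("parcel_%03d", seq_len(n)))
}

# brute-force Spearman: rank both vectors, then Pearson on the ranks
referenceSpearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# spatially smooth maps on the atlas sphere: zero-mean Gaussian process
# with exponential geodesic covariance exp(-d / lambda)
smoothSphereMaps <- function(atlas, nMaps, lambda = 0.3, seed = 1L) {
  cen <- centroids(atlas)
  gd <- acos(pmin(pmax(tcrossprod(cen), -1), 1))
  K <- exp(-gd / lambda) + diag(1e-8, nrow(gd))
  cf <- chol(K)
  set.seed(seed)
  t(matrix(rnorm(nMaps * nrow(cen)), nMaps, nrow(cen)) %*% cf)
}

# dense-matrix AE log-likelihood: builds the full block-diagonal covariance
# and profiles beta and sigma2p by textbook GLS -- the brute-force oracle
# for the blockwise profile likelihood
denseAeLoglik <- function(h2, y, X, ped) {
  n <- length(y)
  V <- diag(n)
  for (f in unique(ped$family_id)) {
    idx <- which(ped$family_id == f)
    if (length(idx) == 2L) {
      rg <- if (ped$zygosity[idx[1]] == "MZ") 1 else 0.5
      V[idx[1], idx[2]] <- V[idx[2], idx[1]] <- h2 * rg
    }
  }
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / n
  as.numeric(-0.5 * (n * log(2 * pi) + n * log(s2) +
                       determinant(V, logarithm = TRUE)$modulus + n))
}
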