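#' Spin-test permutation table
#'
#' Builds `nPerm` spatial permutations of the parcels by drawing a uniform
#' random 3D rotation per permutation, applying it to the left-hemisphere
#' centroids and its x-mirrored version to the right-hemisphere centroids,
#' and reassigning each rotated parcel to an original centroid within its
#' hemisphere by greedy nearest-first one-to-one matching. The resulting
#' permutations preserve the spatial autocorrelation of parcel maps, which
#' a plain shuffle would destroy.
#'
#' @param atlas a [ParcelAtlas] with unit-sphere centroids.
#' @param nPerm number of permutations.
#' @param seed integer seed (table is reproducible).
#' @return nPerm x parcels integer matrix; row `k` maps parcel `i` to the
#'   original parcel index `perm[k, i]`, so a permuted map is
#'   `map[perm[k, ]]`.
#' @export
spinPermute <- function(atlas, nPerm, seed) {
  hemi <- hemispheres(atlas)
  cen <- centroids(atlas)
  idxL <- which(hemi == "L"); idxR <- which(hemi == "R")
  if (length(idxL) < 3L || length(idxR) < 3L)
    stop("need at least 3 parcels per hemisphere")
  mirror <- diag(c(-1, 1, 1))
  withSubstream(seed, "spin-rotations", {
    t(vapply(seq_len(nPerm), function(k) {
      R <- randomRotation()
      perm <- integer(nrow(cen))
      perm[idxL] <- idxL[greedyMatch(cen[idxL, , drop = FALSE] %*% t(R),
                                     cen[idxL, , drop = FALSE])]
      Rr <- mirror %*% R %*% mirror
      perm[idxR] <- idxR[greedyMatch(cen[idxR, , drop = FALSE] %*% t(Rr),
                                     cen[idxR, , drop = FALSE])]
      perm
    }, integer(nrow(cen))))
  })
}

## Uniform random rotation (QR of a Gaussian matrix, sign-fixed, det +1).
randomRotation <- function() {
  qrd <- qr(matrix(rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

## One-to-one assignment of rotated to original positions, taking globally
## nearest pairs first; returns, per rotated row, the matched original row.
greedyMatch <- function(rotated, original) {
  n <- nrow(rotated)
  d2 <- outer(rowSums(rotated^2), rowSums(original^2), `+`) -
    2 * tcrossprod(rotated, original)
  ord <- order(d2)
  rowUsed <- logical(n); colUsed <- logical(n)
  match <- integer(n); left <- n
  for (o in ord) {
    i <- (o - 1L) %% n + 1L
    j <- (o - 1L) %/% n + 1L
    if (rowUsed[i] || colUsed[j]) next
    match[i] <- j; rowUsed[i] <- TRUE; colUsed[j] <- TRUE
    left <- left - 1L
    if (!left) break
  }
  match
}

#' Spin-test correlation between two parcel maps
#'
#' Observed Spearman correlation of the maps against a null built by
#' spatially rotating `mapA` with a [spinPermute()] table while keeping
#' `mapB` fixed; two-sided p-value with the `(1 + k) / (1 + nPerm)`
#' convention, so p is never exactly zero.
#'
#' @param mapA,mapB numeric parcel maps in atlas order.
#' @param atlas a [ParcelAtlas].
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param permTable optional precomputed permutation table (skips
#'   [spinPermute()]).
#' @return a [SpinNull].
#' @export
spinTestCorrelation <- function(mapA, mapB, atlas, nPerm = 1000L, seed = 1L,
                                permTable = NULL) {
  if (sd(mapA, na.rm = TRUE) == 0 || sd(mapB, na.rm = TRUE) == 0)
    stop("cannot spin-test a constant map")
  if (is.null(permTable)) permTable <- spinPermute(atlas, nPerm, seed)
  nPerm <- nrow(permTable)
  obs <- spearmanSafe(mapA, mapB)
  nulls <- vapply(seq_len(nPerm), function(k)
    spearmanSafe(mapA[permTable[k, ]], mapB), numeric(1))
  k <- sum(abs(nulls) >= abs(obs), na.rm = TRUE)
  new("SpinNull", observed = obs, nulls = nulls,
      p = (1 + k) / (1 + nPerm), nPerm = as.numeric(nPerm),
      seed = as.numeric(seed))
}
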