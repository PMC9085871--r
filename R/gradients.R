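#' Row-wise percentile thresholding of a connectome
#'
#' Keeps, per row, the entries at or above that row's `pct` percentile and
#' zeroes the rest — the sparsification applied before the affinity kernel
#' (default: top 10% of each row). The result need not be symmetric. Ties
#' at the threshold all survive, so an all-equal row survives entirely.
#'
#' @param m square numeric matrix.
#' @param pct percentile in (0, 100); default 90.
#' @return matrix of the same size with sub-threshold entries set to zero.
#' @export
thresholdRows <- function(m, pct = 90) {
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (pct <= 0 || pct >= 100) stop("pct must lie in (0, 100)")
  out <- m
  for (i in seq_len(nrow(m))) {
    thr <- quantile(m[i, ], pct / 100, names = FALSE, type = 7)
    out[i, m[i, ] < thr] <- 0
  }
  out
}

#' Normalized-angle affinity kernel
#'
#' Affinity between parcels i and j is `1 - acos(cosine(row_i, row_j)) / pi`:
#' 1 for identical directions, 0.5 for orthogonal rows, 0 for anti-parallel
#' rows. Produces the non-negative symmetric affinity used as input to the
#' diffusion-map embedding.
#'
#' @param m matrix whose rows are parcel connectivity profiles (typically
#'   row-thresholded); all rows must be non-zero.
#' @return symmetric affinity matrix with entries in \[0, 1\].
#' @export
normalizedAngleAffinity <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop(sprintf("zero row for parcel %s",
                 if (is.null(rownames(m))) which(nrm == 0)[1]
                 else rownames(m)[which(nrm == 0)[1]]))
  u <- m / nrm
  cs <- tcrossprod(u)
  cs <- pmin(pmax(cs, -1), 1)
  aff <- 1 - acos(cs) / pi
  (aff + t(aff)) / 2
}

graphComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Density-normalizes the affinity `W' = D^-alpha W D^-alpha`, row-
#' normalizes to the Markov operator, and eigendecomposes. The trivial
#' constant eigenvector is dropped; component k is the k-th non-trivial
#' right eigenvector scaled by `lambda^t`, where `t = 0` is interpreted as
#' the multiscale scaling `lambda / (1 - lambda)` (set
#' `multiscale = FALSE` for the literal `lambda^0 = 1`). `alpha` controls
#' the influence of sampling density (0: maximal, 1: none); the default
#' `alpha = 0.5`, `t = 0` retains global relations and is robust to noise.
#' Components have a deterministic sign (largest-magnitude entry positive).
#' A disconnected affinity is embedded on its largest connected component,
#' with remaining parcels flagged missing (with a warning).
#'
#' @param affinity symmetric non-negative matrix.
#' @param alpha density-normalization exponent in \[0, 1\].
#' @param t diffusion time (>= 0).
#' @param nComponents number of non-trivial components to keep.
#' @param kind label stored in the result ("MPC" or "FC").
#' @param multiscale interpret `t = 0` as multiscale scaling (default TRUE).
#' @param parcelIds optional parcel identifiers.
#' @return a [GradientSet].
#' @export
diffusionMap <- function(affinity, alpha = 0.5, t = 0, nComponents = 10L,
                         kind = "MPC", multiscale = TRUE,
                         parcelIds = rownames(affinity)) {
  n <- nrow(affinity)
  if (ncol(affinity) != n || max(abs(affinity - t(affinity))) > 1e-10)
    stop("affinity must be square and symmetric")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (t < 0) stop("t must be non-negative")
  if (is.null(parcelIds)) parcelIds <- sprintf("parcel_%03d", seq_len(n))

  comp <- graphComponents(affinity)
  keep <- seq_len(n)
  if (max(comp) > 1L) {
    warning("affinity graph is disconnected; embedding the largest component")
    main <- which.max(tabulate(comp))
    keep <- which(comp == main)
  }
  W <- affinity[keep, keep, drop = FALSE]
  d <- rowSums(W)
  Wp <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(Wp)
  S <- Wp / outer(sqrt(d1), sqrt(d1))
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  psi <- eg$vectors / sqrt(d1)          # right eigenvectors of the Markov P
  nc <- min(nComponents, length(keep) - 1L)
  lamK <- lam[1L + seq_len(nc)]
  comps <- psi[, 1L + seq_len(nc), drop = FALSE]
  scaleK <- if (t == 0 && multiscale) lamK / (1 - pmin(lamK, 1 - 1e-12))
            else lamK^t
  comps <- sweep(comps, 2L, scaleK, `*`)
  for (j in seq_len(nc)) {              # deterministic sign convention
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  full <- matrix(NA_real_, n, nc)
  full[keep, ] <- comps
  new("GradientSet", components = full, eigenvalues = lamK,
      kind = kind, alignment = "raw", parcelIds = parcelIds)
}

#' Gradients of a connectome in one call
#'
#' Row-thresholds the matrix (default top 10%), applies the normalized-
#' angle kernel and runs the diffusion-map embedding.
#'
#' @param conn a [ConnectivityMatrix].
#' @param pct row-threshold percentile (default 90).
#' @inheritParams diffusionMap
#' @return a [GradientSet].
#' @export
connectomeGradients <- function(conn, pct = 90, alpha = 0.5, t = 0,
                                nComponents = 10L, multiscale = TRUE) {
  kind <- if (connKind(conn) == "MPC") "MPC" else "FC"
  aff <- normalizedAngleAffinity(thresholdRows(conn@mat, pct))
  diffusionMap(aff, alpha = alpha, t = t, nComponents = nComponents,
               kind = kind, multiscale = multiscale,
               parcelIds = parcelIds(conn))
}

#' Procrustes alignment of gradient components
#'
#' Finds the orthogonal rotation (no scaling) of the source components that
#' minimizes the Frobenius distance to the reference components, and
#' applies it. A rank-deficient cross-product falls back to the identity
#' with a warning.
#'
#' @param source,reference [GradientSet] objects with equal parcel count
#'   and component count.
#' @return the aligned source [GradientSet].
#' @export
procrustesAlign <- function(source, reference) {
  A <- source@components; B <- reference@components
  if (!all(dim(A) == dim(B)))
    stop("source and reference must have identical dimensions")
  ok <- stats::complete.cases(A) & stats::complete.cases(B)
  sv <- svd(crossprod(A[ok, , drop = FALSE], B[ok, , drop = FALSE]))
  if (min(sv$d) < 1e-12 * max(sv$d, 1)) {
    warning("rank-deficient cross-product; falling back to identity rotation")
    R <- diag(ncol(A))
  } else R <- sv$u %*% t(sv$v)
  out <- source
  out@components <- A %*% R
  out@alignment <- paste0("procrustes-to-", reference@kind)
  out
}

#' Gradient-difference map
#'
#' Z-standardizes the selected component of each gradient set across
#' parcels and returns `delta = z(FC) - z(MPC)` per parcel. When an atlas
#' is supplied, both components are first sign-oriented so that the
#' idiotypic-class mean is negative, fixing the sign ambiguity of
#' eigenvector orientation before subtraction.
#'
#' @param gMpc,gFc aligned [GradientSet] objects (MPC and FC).
#' @param component component index (default 1, the principal gradient).
#' @param atlas optional [ParcelAtlas] used for sign orientation.
#' @return named numeric parcel map of differences.
#' @export
gradientDifference <- function(gMpc, gFc, component = 1L, atlas = NULL) {
  za <- zstandardize(gMpc@components[, component])
  zb <- zstandardize(gFc@components[, component])
  if (!is.null(atlas)) {
    idio <- classLabels(atlas) == "idiotypic"
    if (mean(za[idio], na.rm = TRUE) > 0) za <- -za
    if (mean(zb[idio], na.rm = TRUE) > 0) zb <- -zb
  }
  setNames(zb - za, gMpc@parcelIds)
}

#' Select the homolog gradient for a reference map
#'
#' Returns the candidate component whose Spearman correlation with the
#' reference map has the largest magnitude, together with the sign needed
#' to match the reference orientation.
#'
#' @param candidate a [GradientSet].
#' @param referenceMap numeric parcel map.
#' @return list with `component` (index), `sign` (+1/-1) and `rho`.
#' @export
selectHomologGradient <- function(candidate, referenceMap) {
  rhos <- apply(candidate@components, 2L, spearmanSafe, y = referenceMap)
  k <- which.max(abs(rhos))
  list(component = k, sign = if (rhos[k] >= 0) 1 else -1, rho = rhos[k])
}
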