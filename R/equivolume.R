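#' Equivolumetric depth fraction
#'
#' Position of an intracortical surface between the inner (white) and outer
#' (pial) surface such that a fraction `alpha` of the local cortical volume
#' lies above it. The construction compensates for cortical folding: where
#' the outer surface is locally larger than the inner one (gyral crowns) the
#' surface sits deeper than the equidistant position, and vice versa in
#' sulci. With local surface areas \eqn{A_{in}} and \eqn{A_{out}},
#' \deqn{\rho = \frac{1}{A_{out}-A_{in}}\left(-A_{in} +
#'   \sqrt{\alpha A_{out}^2 + (1-\alpha) A_{in}^2}\right).}
#' The equal-area case is the analytic limit \eqn{\rho = \alpha}; it is used
#' whenever \eqn{|A_{out}-A_{in}| < 10^{-9} A_{in}} to remove the removable
#' singularity.
#'
#' @param aIn,aOut strictly positive local inner/outer surface areas
#'   (any consistent units); vectors are recycled against `alpha`.
#' @param alpha volume fraction(s) in \[0, 1\].
#' @return depth fraction(s) \eqn{\rho \in [0,1]}, 0 at the inner surface
#'   for `alpha = 0` and 1 at the outer surface for `alpha = 1`.
#' @examples
#' equivolumetricFraction(1, 3, 0.5)   # (sqrt(5) - 1) / 2
#' equivolumetricFraction(2, 2, 0.3)   # equal-area limit: 0.3
#' @export
equivolumetricFraction <- function(aIn, aOut, alpha) {
  if (any(aIn <= 0) || any(aOut <= 0))
    stop("surface areas must be strictly positive")
  if (any(alpha < 0 | alpha > 1))
    stop("alpha must lie in [0, 1]")
  n <- max(length(aIn), length(aOut), length(alpha))
  aIn <- rep_len(aIn, n); aOut <- rep_len(aOut, n); alpha <- rep_len(alpha, n)
  rho <- alpha
  gen <- abs(aOut - aIn) >= 1e-9 * aIn
  if (any(gen)) {
    rho[gen] <- (-aIn[gen] +
                   sqrt(alpha[gen] * aOut[gen]^2 + (1 - alpha[gen]) * aIn[gen]^2)) /
      (aOut[gen] - aIn[gen])
  }
  rho
}

#' Volume-fraction grid for a stack of intracortical surfaces
#'
#' Returns `nSurfaces` volume fractions strictly between the boundaries,
#' `alpha_k = k / (nSurfaces + 1)`. Surfaces sit strictly between the pial
#' and white boundaries, avoiding boundary partial-volume samples.
#'
#' @param nSurfaces number of surfaces (>= 2); 12 for human-like runs,
#'   9 for macaque-like runs.
#' @return strictly increasing numeric vector in (0, 1).
#' @export
fractionGrid <- function(nSurfaces) {
  if (length(nSurfaces) != 1L || nSurfaces < 2L)
    stop("nSurfaces must be a single integer >= 2")
  seq_len(nSurfaces) / (nSurfaces + 1)
}

#' Sample depth-wise intensity profiles
#'
#' Evaluates a per-vertex intensity model at a set of depth fractions,
#' producing one value per (vertex, surface). Surface index 1 is the surface
#' nearest the outer boundary (smallest fraction). The intensity model is
#' either a function of depth on \[0, 1\] (one function shared by all
#' vertices, or a list of per-vertex functions) or a depth-indexed table
#' (`depths` plus a vertices x depths `values` matrix) interpolated
#' linearly.
#'
#' @param intensity a function `f(depth)`, a list of such functions (one per
#'   vertex), or a list with elements `depths` (increasing vector) and
#'   `values` (vertices x length(depths) matrix).
#' @param fractions numeric vector of depth fractions shared by all
#'   vertices, or a vertices x surfaces matrix of per-vertex fractions.
#' @param nVertices required when `intensity` is a single function and
#'   `fractions` is a vector.
#' @return vertices x surfaces numeric matrix of sampled intensities.
#' @export
sampleProfiles <- function(intensity, fractions, nVertices = NULL) {
  fracMat <- if (is.matrix(fractions)) fractions else NULL
  fvec <- if (is.null(fracMat)) as.numeric(fractions) else NULL

  evalAt <- function(f, x) vapply(x, f, numeric(1))

  if (is.function(intensity)) {
    if (is.null(fracMat)) {
      if (is.null(nVertices))
        stop("nVertices required for a shared intensity function")
      checkRange(fvec)
      row <- evalAt(intensity, fvec)
      return(matrix(row, nrow = nVertices, ncol = length(fvec), byrow = TRUE))
    }
    checkRange(fracMat)
    return(t(apply(fracMat, 1L, function(r) evalAt(intensity, r))))
  }

  if (is.list(intensity) && !is.null(intensity$depths)) {
    d <- intensity$depths; v <- intensity$values
    if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
    getFr <- function(i) if (is.null(fracMat)) fvec else fracMat[i, ]
    out <- t(vapply(seq_len(nrow(v)), function(i) {
      fr <- getFr(i)
      if (any(fr < min(d) - 1e-12) || any(fr > max(d) + 1e-12))
        stop("fraction outside the provided depth range")
      stats::approx(d, v[i, ], xout = fr, rule = 1)$y
    }, numeric(if (is.null(fracMat)) length(fvec) else ncol(fracMat))))
    return(out)
  }

  if (is.list(intensity)) {          # one callable per vertex
    nv <- length(intensity)
    out <- matrix(NA_real_, nv, if (is.null(fracMat)) length(fvec) else ncol(fracMat))
    for (i in seq_len(nv)) {
      fr <- if (is.null(fracMat)) fvec else fracMat[i, ]
      checkRange(fr)
      out[i, ] <- evalAt(intensity[[i]], fr)
    }
    return(out)
  }
  stop("unsupported intensity model")
}

checkRange <- function(fr) {
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    stop("fraction outside the provided depth range [0, 1]")
  invisible(fr)
}

#' Average vertex profiles into parcel profile matrices
#'
#' Per-depth unweighted mean of the unmasked vertices in each parcel. Also
#' attaches the cortex-wide mean profile (unweighted mean over parcels) as
#' the `"cortexProfile"` attribute — the reference profile `c` used by the
#' MPC partial correlation.
#'
#' @param profiles vertices x depths matrix (one subject).
#' @param vertexParcel integer parcel index per vertex; `NA` masks a vertex.
#' @param nParcels total parcel count (defaults to `max(vertexParcel)`).
#' @param parcelIds optional rownames for the result.
#' @return parcels x depths matrix with attribute `cortexProfile`.
#' @export
parcelMeanProfiles <- function(profiles, vertexParcel,
                               nParcels = max(vertexParcel, na.rm = TRUE),
                               parcelIds = NULL) {
  if (nrow(profiles) != length(vertexParcel))
    stop("one parcel label per vertex required")
  out <- matrix(NA_real_, nParcels, ncol(profiles))
  for (p in seq_len(nParcels)) {
    idx <- which(vertexParcel == p)
    if (!length(idx))
      stop(sprintf("parcel %s has zero unmasked vertices",
                   if (is.null(parcelIds)) p else parcelIds[p]))
    out[p, ] <- colMeans(profiles[idx, , drop = FALSE])
  }
  if (!is.null(parcelIds)) rownames(out) <- parcelIds
  attr(out, "cortexProfile") <- colMeans(out)
  out
}
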