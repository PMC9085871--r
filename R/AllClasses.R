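#' ParcelAtlas: parcel identifiers, cytoarchitectural classes and centroids
#'
#' Container shared by all pipeline stages. Parcel order in the atlas is the
#' canonical order for every matrix and map in the package. Each parcel
#' carries one of the four cytoarchitectural classes of the sensory-fugal
#' hierarchy (idiotypic, unimodal, heteromodal, paralimbic), a hemisphere
#' label, and a unit-sphere centroid used by the spin-test nulls.
#'
#' @slot parcelIds character vector of parcel identifiers (canonical order).
#' @slot classLabel factor with levels idiotypic/unimodal/heteromodal/paralimbic.
#' @slot centroid numeric matrix (parcels x 3) of unit-norm sphere coordinates.
#' @slot hemisphere factor with levels L/R.
#' @exportClass ParcelAtlas
setClass("ParcelAtlas",
  representation(
    parcelIds  = "character",
    classLabel = "factor",
    centroid   = "matrix",
    hemisphere = "factor"
  )
)

setValidity("ParcelAtlas", function(object) {
  n <- length(object@parcelIds)
  msg <- character()
  if (anyDuplicated(object@parcelIds))
    msg <- c(msg, "parcel ids must be unique")
  if (length(object@classLabel) != n || anyNA(object@classLabel))
    msg <- c(msg, "every parcel needs exactly one class label")
  if (!all(levels(object@classLabel) == CLASS_LEVELS))
    msg <- c(msg, "class levels must be idiotypic/unimodal/heteromodal/paralimbic")
  if (!is.numeric(object@centroid) || nrow(object@centroid) != n ||
      ncol(object@centroid) != 3L)
    msg <- c(msg, "centroid must be a parcels x 3 numeric matrix")
  else {
    nrm <- sqrt(rowSums(object@centroid^2))
    if (any(abs(nrm - 1) > 1e-9))
      msg <- c(msg, "centroids must have unit norm (tolerance 1e-9)")
  }
  if (length(object@hemisphere) != n ||
      !all(levels(object@hemisphere) %in% c("L", "R")))
    msg <- c(msg, "hemisphere must be a length-n factor with levels L/R")
  if (length(msg)) msg else TRUE
})

#' ToyCortex: a synthetic cortex with vertex-level geometry
#'
#' A [ParcelAtlas] plus the per-vertex fields the equivolumetric sampler
#' needs: a parcel label and local inner/outer surface areas per vertex.
#'
#' @slot atlas a [ParcelAtlas].
#' @slot vertexParcel integer vector mapping each vertex to a parcel index.
#' @slot innerArea,outerArea strictly positive per-vertex local surface areas.
#' @exportClass ToyCortex
setClass("ToyCortex",
  representation(
    atlas       = "ParcelAtlas",
    vertexParcel = "integer",
    innerArea   = "numeric",
    outerArea   = "numeric"
  )
)

setValidity("ToyCortex", function(object) {
  nv <- length(object@vertexParcel)
  msg <- character()
  if (length(object@innerArea) != nv || length(object@outerArea) != nv)
    msg <- c(msg, "area fields must match the number of vertices")
  if (any(object@innerArea <= 0) || any(object@outerArea <= 0))
    msg <- c(msg, "vertex areas must be strictly positive")
  np <- length(object@atlas@parcelIds)
  if (nv && (min(object@vertexParcel) < 1L || max(object@vertexParcel) > np))
    msg <- c(msg, "vertexParcel indices out of range")
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: a symmetric parcel-by-parcel connectome
#'
#' Holds either a microstructure profile covariance (MPC) matrix — partial
#' correlations of depth-wise intensity profiles controlling for the
#' cortex-wide mean profile — or a Fisher-z resting-state functional
#' connectivity (FC_z) matrix. The diagonal is set to zero for both kinds
#' and excluded from row-wise statistics.
#'
#' @slot mat symmetric numeric matrix, parcels x parcels, zero diagonal.
#' @slot kind "MPC" or "FC_z".
#' @slot subject subject identifier or "group-mean".
#' @slot parcelIds parcel identifiers fixing row/column order.
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(
    mat       = "matrix",
    kind      = "character",
    subject   = "character",
    parcelIds = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (length(object@parcelIds) != nrow(m))
    msg <- c(msg, "parcelIds length must equal matrix dimension")
  if (!object@kind %in% c("MPC", "FC_z"))
    msg <- c(msg, "kind must be 'MPC' or 'FC_z'")
  if (max(abs(m - t(m))) > 1e-10)
    msg <- c(msg, "matrix must be symmetric to 1e-10")
  if (any(!is.finite(m)))
    msg <- c(msg, "all entries must be finite")
  if (any(diag(m) != 0))
    msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})

#' TwinCohort: pedigree, covariates and phenotypes for twin analysis
#'
#' MZ and DZ families contain exactly two members; singletons are sole
#' members of their family. Phenotypes are stored as a subjects x phenotypes
#' matrix in pedigree row order.
#'
#' @slot pedigree data.frame with columns subject_id, family_id, zygosity
#'   (MZ/DZ/singleton), age (years, positive), sex (0/1).
#' @slot phenotypes numeric matrix, subjects x phenotypes, named columns.
#' @exportClass TwinCohort
setClass("TwinCohort",
  representation(pedigree = "data.frame", phenotypes = "matrix")
)

setValidity("TwinCohort", function(object) {
  ped <- object@pedigree
  msg <- character()
  need <- c("subject_id", "family_id", "zygosity", "age", "sex")
  if (!all(need %in% names(ped)))
    return(paste("pedigree must have columns", paste(need, collapse = ", ")))
  if (!all(ped$zygosity %in% c("MZ", "DZ", "singleton")))
    msg <- c(msg, "zygosity must be MZ, DZ or singleton")
  if (any(ped$age <= 0)) msg <- c(msg, "ages must be positive")
  sizes <- table(ped$family_id)
  twin <- unique(ped$family_id[ped$zygosity %in% c("MZ", "DZ")])
  sing <- unique(ped$family_id[ped$zygosity == "singleton"])
  if (any(sizes[twin] != 2L))
    msg <- c(msg, "MZ/DZ families must contain exactly 2 members")
  if (any(sizes[sing] != 1L))
    msg <- c(msg, "singletons must be sole members of their family")
  if (nrow(object@phenotypes) != nrow(ped))
    msg <- c(msg, "phenotype rows must match pedigree rows")
  if (length(msg)) msg else TRUE
})

#' GradientSet: eigenvectors and eigenvalues of a diffusion-map embedding
#'
#' @slot components parcels x n_components matrix of gradient scores.
#' @slot eigenvalues non-increasing eigenvalues of the Markov operator
#'   (trivial unit eigenvalue removed).
#' @slot kind source modality, "MPC" or "FC".
#' @slot alignment "raw" or "procrustes-to-<ref>".
#' @slot parcelIds parcel identifiers fixing row order.
#' @exportClass GradientSet
setClass("GradientSet",
  representation(
    components  = "matrix",
    eigenvalues = "numeric",
    kind        = "character",
    alignment   = "character",
    parcelIds   = "character"
  )
)

setValidity("GradientSet", function(object) {
  msg <- character()
  if (ncol(object@components) != length(object@eigenvalues))
    msg <- c(msg, "one eigenvalue per component required")
  if (length(object@parcelIds) &&
      length(object@parcelIds) != nrow(object@components))
    msg <- c(msg, "parcelIds must match component rows")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' HeritabilityEstimate: AE maximum-likelihood variance decomposition
#'
#' @slot h2 narrow-sense heritability, sigma2_g / sigma2_p, in [0,1].
#' @slot sigma2g,sigma2e,sigma2p variance components (phenotype units^2).
#' @slot beta covariate coefficients (intercept, age, sex, age^2, age x sex).
#' @slot loglik maximized log-likelihood.
#' @slot p likelihood-ratio p-value against the E-only model (boundary
#'   half-half chi-square mixture).
#' @slot seH2 standard error of h2 from numerical observed information
#'   (NA at the boundary).
#' @exportClass HeritabilityEstimate
setClass("HeritabilityEstimate",
  representation(
    h2 = "numeric", sigma2g = "numeric", sigma2e = "numeric",
    sigma2p = "numeric", beta = "numeric", loglik = "numeric",
    p = "numeric", seH2 = "numeric"
  )
)

setValidity("HeritabilityEstimate", function(object) {
  msg <- character()
  if (object@h2 < -1e-9 || object@h2 > 1 + 1e-9)
    msg <- c(msg, "h2 must lie in [0,1]")
  if (object@sigma2e < -1e-9) msg <- c(msg, "sigma2e must be non-negative")
  sp <- object@sigma2g + object@sigma2e
  if (sp > 0 && abs(object@h2 - object@sigma2g / sp) > 1e-9)
    msg <- c(msg, "h2 must equal sigma2g / sigma2p")
  if (length(msg)) msg else TRUE
})

#' SpinNull: a spin-test permutation null for a map-to-map correlation
#'
#' @slot observed observed Spearman correlation.
#' @slot nulls vector of null correlations (one per spin).
#' @slot p two-sided p with the (1 + k)/(1 + n_perm) convention.
#' @slot nPerm number of permutations.
#' @slot seed seed used for the rotation draws.
#' @exportClass SpinNull
setClass("SpinNull",
  representation(
    observed = "numeric", nulls = "numeric", p = "numeric",
    nPerm = "numeric", seed = "numeric"
  )
)

setValidity("SpinNull", function(object) {
  k <- sum(abs(object@nulls) >= abs(object@observed))
  pref <- (1 + k) / (1 + object@nPerm)
  if (abs(object@p - pref) > 1e-12)
    return("p must follow the (1 + k)/(1 + n_perm) convention")
  TRUE
})
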