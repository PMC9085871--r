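#' @rdname ParcelAtlas-class
#' @param object,x a couplemap S4 object
#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' @rdname ParcelAtlas-class
#' @export
setGeneric("nParcels", function(x) standardGeneric("nParcels"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connKind", function(x) standardGeneric("connKind"))

#' @rdname GradientSet-class
#' @export
setGeneric("gradientComponents", function(x) standardGeneric("gradientComponents"))

#' @rdname GradientSet-class
#' @export
setGeneric("gradientEigenvalues", function(x) standardGeneric("gradientEigenvalues"))

#' @rdname TwinCohort-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname TwinCohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

setMethod("parcelIds", "ParcelAtlas", function(x) x@parcelIds)
setMethod("classLabels", "ParcelAtlas", function(x)
  setNames(x@classLabel, x@parcelIds))
setMethod("centroids", "ParcelAtlas", function(x) {
  m <- x@centroid
  rownames(m) <- x@parcelIds
  colnames(m) <- c("x", "y", "z")
  m
})
setMethod("hemispheres", "ParcelAtlas", function(x)
  setNames(x@hemisphere, x@parcelIds))
setMethod("nParcels", "ParcelAtlas", function(x) length(x@parcelIds))

setMethod("parcelIds", "ToyCortex", function(x) x@atlas@parcelIds)
setMethod("nParcels", "ToyCortex", function(x) length(x@atlas@parcelIds))

setMethod("parcelIds", "ConnectivityMatrix", function(x) x@parcelIds)
setMethod("connMatrix", "ConnectivityMatrix", function(x) {
  m <- x@mat
  dimnames(m) <- list(x@parcelIds, x@parcelIds)
  m
})
setMethod("connKind", "ConnectivityMatrix", function(x) x@kind)

setMethod("parcelIds", "GradientSet", function(x) x@parcelIds)
setMethod("gradientComponents", "GradientSet", function(x) {
  m <- x@components
  rownames(m) <- x@parcelIds
  colnames(m) <- paste0("G", seq_len(ncol(m)))
  m
})
setMethod("gradientEigenvalues", "GradientSet", function(x) x@eigenvalues)

setMethod("pedigree", "TwinCohort", function(x) x@pedigree)
setMethod("phenotypes", "TwinCohort", function(x) x@phenotypes)

setMethod("show", "ParcelAtlas", function(object) {
  cat("ParcelAtlas with", length(object@parcelIds), "parcels\n")
  print(table(class = object@classLabel, hemisphere = object@hemisphere))
})

setMethod("show", "ToyCortex", function(object) {
  cat("ToyCortex:", length(object@vertexParcel), "vertices over",
      length(object@atlas@parcelIds), "parcels\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix [%s] %d x %d, subject: %s\n",
              object@kind, nrow(object@mat), ncol(object@mat), object@subject))
})

setMethod("show", "TwinCohort", function(object) {
  z <- table(object@pedigree$zygosity)
  cat(sprintf(
    "TwinCohort: %d subjects (%d MZ, %d DZ, %d singletons), %d phenotype(s)\n",
    nrow(object@pedigree),
    if ("MZ" %in% names(z)) z[["MZ"]] else 0L,
    if ("DZ" %in% names(z)) z[["DZ"]] else 0L,
    if ("singleton" %in% names(z)) z[["singleton"]] else 0L,
    ncol(object@phenotypes)))
})

setMethod("show", "GradientSet", function(object) {
  cat(sprintf("GradientSet [%s] %d parcels x %d components (%s)\n",
              object@kind, nrow(object@components),
              ncol(object@components), object@alignment))
  cat("eigenvalues:", signif(object@eigenvalues, 4), "\n")
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf(
    "AE heritability: h2 = %.3f (SE %.3f), sigma2g = %.3f, sigma2e = %.3f\n",
    object@h2, object@seH2, object@sigma2g, object@sigma2e))
  cat(sprintf("  loglik = %.3f, LRT p = %.4g\n", object@loglik, object@p))
})

setMethod("show", "SpinNull", function(object) {
  cat(sprintf("SpinNull: observed = %.4f, p_spin = %.4g (%d permutations)\n",
              object@observed, object@p, as.integer(object@nPerm)))
})
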