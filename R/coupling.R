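#' Node-wise structure-function coupling
#'
#' Per parcel, the Spearman rank correlation between that parcel's row in
#' one connectome and its row in another (typically group-mean MPC vs
#' group-mean Fisher-z FC), excluding the diagonal entry. A parcel whose
#' row is constant in either matrix gets a missing value.
#'
#' @param a,b [ConnectivityMatrix] objects with identical parcel order.
#' @return named numeric vector (a parcel map), one value per parcel.
#' @export
rowwiseCoupling <- function(a, b) {
  if (!identical(parcelIds(a), parcelIds(b)))
    stop("matrices must share the same parcel order")
  ma <- a@mat; mb <- b@mat
  n <- nrow(ma)
  out <- vapply(seq_len(n), function(i)
    spearmanSafe(ma[i, -i], mb[i, -i]), numeric(1))
  setNames(out, parcelIds(a))
}

#' Genetic coupling of mean connectivity with edge heritability
#'
#' Per parcel, the Spearman correlation of the parcel's mean connectivity
#' row with the corresponding row of the edge-wise heritability matrix,
#' diagonal excluded.
#'
#' @param meanMatrix group-mean [ConnectivityMatrix].
#' @param h2Matrix symmetric matrix of edge heritabilities in the same
#'   parcel order (e.g., from [edgeValuesToMatrix()]), or a
#'   [ConnectivityMatrix]-shaped plain matrix.
#' @return named numeric parcel map.
#' @export
geneticCoupling <- function(meanMatrix, h2Matrix) {
  ma <- meanMatrix@mat
  mh <- if (is(h2Matrix, "ConnectivityMatrix")) h2Matrix@mat else h2Matrix
  if (!all(dim(ma) == dim(mh)))
    stop("matrices must have identical dimensions")
  n <- nrow(ma)
  out <- vapply(seq_len(n), function(i)
    spearmanSafe(ma[i, -i], mh[i, -i]), numeric(1))
  setNames(out, parcelIds(meanMatrix))
}

#' Class-wise summary of a parcel map
#'
#' Mean and sample standard deviation (n - 1 denominator) of a parcel map
#' within each cytoarchitectural class, missing parcels dropped.
#'
#' @param map named numeric parcel map in atlas order.
#' @param atlas a [ParcelAtlas].
#' @return data.frame with columns class, n, mean, sd.
#' @export
classSummary <- function(map, atlas) {
  cls <- classLabels(atlas)
  if (length(map) != nParcels(atlas))
    stop("map length must equal the atlas parcel count")
  rows <- lapply(CLASS_LEVELS, function(cl) {
    v <- map[cls == cl]
    v <- v[is.finite(v)]
    if (!length(v)) stop(sprintf("class %s has no parcels with values", cl))
    data.frame(class = cl, n = length(v), mean = mean(v), sd = sd(v))
  })
  do.call(rbind, rows)
}

#' Contrast a parcel map between two cytoarchitectural classes
#'
#' Welch (unequal-variance) two-sample t-test of the map values in
#' `classA` against `classB`, with the p-value Bonferroni-multiplied by the
#' number of classes compared (4 by default) and capped at 1, the usual
#' reporting convention for class-wise tables in this literature.
#'
#' @param map named numeric parcel map.
#' @param atlas a [ParcelAtlas].
#' @param classA,classB class names.
#' @param nComparisons Bonferroni multiplier (default 4).
#' @return list with `t`, `df`, `p` (uncorrected) and `pCorrected`.
#' @export
classContrast <- function(map, atlas, classA, classB, nComparisons = 4L) {
  cls <- classLabels(atlas)
  va <- map[cls == classA]; va <- va[is.finite(va)]
  vb <- map[cls == classB]; vb <- vb[is.finite(vb)]
  if (length(va) < 2L || length(vb) < 2L)
    stop("each class needs at least 2 parcels with values")
  na <- length(va); nb <- length(vb)
  sa2 <- var(va); sb2 <- var(vb)
  se2 <- sa2 / na + sb2 / nb
  tstat <- if (se2 == 0) 0 else (mean(va) - mean(vb)) / sqrt(se2)
  df <- if (se2 == 0) na + nb - 2
        else se2^2 / ((sa2 / na)^2 / (na - 1) + (sb2 / nb)^2 / (nb - 1))
  p <- if (tstat == 0) 1 else 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(t = tstat, df = df, p = p,
       pCorrected = min(1, p * nComparisons))
}
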