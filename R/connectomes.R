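#' Subject-level microstructure profile covariance (MPC)
#'
#' Pairwise partial correlation of parcel depth profiles, controlling for
#' the cortex-wide mean profile `c`:
#' \deqn{MPC(i,j) = \frac{r_{ij} - r_{ic} r_{jc}}
#'   {\sqrt{(1 - r_{ic}^2)(1 - r_{jc}^2)}}}
#' with `r` Pearson correlations across depths. Negative values are retained
#' by default; `threshold = TRUE` reproduces the zero-thresholded variant of
#' the earlier MPC literature. The diagonal is set to zero.
#'
#' @param profileMatrix parcels x depths matrix (>= 3 depths); the
#'   cortex-wide profile is taken from its `cortexProfile` attribute when
#'   present, else computed as the unweighted parcel mean.
#' @param subject subject identifier stored in the result.
#' @param parcelIds optional parcel identifiers (default: rownames).
#' @param threshold if TRUE, negative MPC values are set to zero.
#' @return a [ConnectivityMatrix] of kind "MPC".
#' @export
mpcSubject <- function(profileMatrix, subject = "subject",
                       parcelIds = rownames(profileMatrix),
                       threshold = FALSE) {
  if (ncol(profileMatrix) < 3L)
    stop("at least 3 depths are required")
  n <- nrow(profileMatrix)
  if (is.null(parcelIds)) parcelIds <- sprintf("parcel_%03d", seq_len(n))
  sds <- apply(profileMatrix, 1L, sd)
  if (any(sds == 0))
    stop(sprintf("constant (zero-variance) profile for parcel %s",
                 parcelIds[which(sds == 0)[1]]))
  cprof <- attr(profileMatrix, "cortexProfile")
  if (is.null(cprof)) cprof <- colMeans(profileMatrix)
  rij <- cor(t(profileMatrix))
  ric <- as.numeric(cor(t(profileMatrix), cprof))
  if (any(abs(ric) >= 1 - 1e-12))
    stop(sprintf(
      "degenerate profile: parcel %s is perfectly correlated with the cortex-wide mean",
      parcelIds[which(abs(ric) >= 1 - 1e-12)[1]]))
  denom <- sqrt(outer(1 - ric^2, 1 - ric^2))
  m <- (rij - outer(ric, ric)) / denom
  m <- (m + t(m)) / 2
  if (threshold) m[m < 0] <- 0
  diag(m) <- 0
  new("ConnectivityMatrix", mat = unname(m), kind = "MPC",
      subject = as.character(subject), parcelIds = parcelIds)
}

#' Group-average connectivity
#'
#' Element-wise arithmetic mean of subject matrices (the subject average of
#' the MPC definition, or the mean of Fisher-z FC matrices).
#'
#' @param matrices list of [ConnectivityMatrix] objects with identical kind
#'   and parcel order.
#' @return a [ConnectivityMatrix] with subject `"group-mean"`.
#' @export
groupMean <- function(matrices) {
  if (!length(matrices)) stop("at least one subject matrix is required")
  ids <- parcelIds(matrices[[1]])
  kind <- connKind(matrices[[1]])
  for (m in matrices) {
    if (!identical(parcelIds(m), ids))
      stop("all matrices must share the same parcel order")
    if (!identical(connKind(m), kind))
      stop("all matrices must share the same kind")
  }
  acc <- Reduce(`+`, lapply(matrices, function(m) m@mat))
  new("ConnectivityMatrix", mat = acc / length(matrices), kind = kind,
      subject = "group-mean", parcelIds = ids)
}

#' @rdname groupMean
#' @param ... passed through to [groupMean()].
#' @export
mpcGroup <- function(matrices, ...) {
  if (any(vapply(matrices, connKind, character(1)) != "MPC"))
    stop("mpcGroup expects MPC matrices")
  groupMean(matrices)
}

#' Subject-level Fisher-z functional connectivity
#'
#' Pairwise Pearson correlation of parcel timeseries, Fisher transformed
#' (`atanh`). Correlations are clipped to +/-(1 - 1e-7) beforehand so that
#' perfectly (anti)correlated synthetic series stay finite. Diagonal zero.
#'
#' @param timeseries timepoints x parcels matrix, T >= 3.
#' @param subject subject identifier stored in the result.
#' @param parcelIds optional parcel identifiers (default: colnames).
#' @return a [ConnectivityMatrix] of kind "FC_z".
#' @export
fcSubject <- function(timeseries, subject = "subject",
                      parcelIds = colnames(timeseries)) {
  if (nrow(timeseries) < 3L) stop("at least 3 timepoints are required")
  n <- ncol(timeseries)
  if (is.null(parcelIds)) parcelIds <- sprintf("parcel_%03d", seq_len(n))
  sds <- apply(timeseries, 2L, sd)
  if (any(sds == 0))
    stop(sprintf("constant timeseries for parcel %s",
                 parcelIds[which(sds == 0)[1]]))
  r <- cor(timeseries)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  new("ConnectivityMatrix", mat = unname(z), kind = "FC_z",
      subject = as.character(subject), parcelIds = parcelIds)
}

#' @rdname groupMean
#' @export
fcGroup <- function(matrices, ...) {
  if (any(vapply(matrices, connKind, character(1)) != "FC_z"))
    stop("fcGroup expects FC_z matrices")
  groupMean(matrices)
}
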