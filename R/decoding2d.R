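#' Quadrant assignment in the 2D coupling space
#'
#' Places each parcel in the two-dimensional coordinate system with the
#' gradient-difference map on x and structure-function coupling on y. Both
#' maps are z-standardized, then quadrants are assigned by sign relative to
#' configurable thresholds: `y > y0` upper, `x < x0` left.
#'
#' @param xMap,yMap numeric parcel maps sharing parcel order.
#' @param x0,y0 thresholds on the standardized axes (default 0).
#' @param standardize z-standardize each axis first (default TRUE). Set to
#'   FALSE when the maps are already on a common scale — e.g., when two
#'   groups are compared in one shared coordinate system and were
#'   standardized jointly, so that group shifts remain visible.
#' @return list with `quadrant` (named factor UL/UR/LL/LR), standardized
#'   `x` and `y`, and the thresholds used. Parcels missing on either axis
#'   get `NA`.
#' @export
assignQuadrants <- function(xMap, yMap, x0 = 0, y0 = 0, standardize = TRUE) {
  if (length(xMap) != length(yMap))
    stop("maps must share parcels")
  zx <- if (standardize) zstandardize(xMap) else xMap
  zy <- if (standardize) zstandardize(yMap) else yMap
  q <- ifelse(zy > y0,
              ifelse(zx < x0, "UL", "UR"),
              ifelse(zx < x0, "LL", "LR"))
  q[!is.finite(zx) | !is.finite(zy)] <- NA
  list(quadrant = setNames(factor(q, levels = c("UL", "UR", "LL", "LR")),
                           names(xMap)),
       x = zx, y = zy, x0 = x0, y0 = y0)
}

#' Quadrant counts
#'
#' @param assignment result of [assignQuadrants()].
#' @return named integer vector of counts over UL/UR/LL/LR.
#' @export
quadrantCounts <- function(assignment) {
  table(assignment$quadrant)
}

#' Chi-square comparison of quadrant occupancy between two groups
#'
#' Pearson chi-square (no continuity correction) on the 2 x k contingency
#' table of counts, df = k - 1 — the comparison used to contrast how two
#' groups distribute their parcels over the quadrants.
#'
#' @param countsGroup1,countsGroup2 non-negative count vectors of equal
#'   length k.
#' @return list with `chisq`, `df`, `p`.
#' @export
quadrantChisq <- function(countsGroup1, countsGroup2) {
  if (length(countsGroup1) != length(countsGroup2))
    stop("count vectors must have equal length")
  tab <- rbind(as.numeric(countsGroup1), as.numeric(countsGroup2))
  if (any(tab < 0)) stop("counts must be non-negative")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0)) stop("expected cell count of zero")
  chisq <- sum((tab - E)^2 / E)
  df <- ncol(tab) - 1L
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Binned weighted-average term ranking along an axis
#'
#' Sorts parcels along an axis map, groups them into `nBins` equally sized
#' bins (rank-based; ties broken by parcel index; sizes differ by at most
#' one), averages each term's scores per bin, and computes each term's
#' weighted mean position `sum(bin * weight) / sum(weight)`. By default the
#' per-term bin means are shifted to be non-negative (subtracting the
#' minimum bin mean) before weighting, since a weighted average is
#' undefined for negative z-scores; `shift = FALSE` uses the raw means.
#' Terms are ranked by descending weighted position (rank 1 = closest to
#' the top of the axis), ties broken by term name; an all-zero term gets a
#' missing rank.
#'
#' @param termMaps parcels x terms numeric matrix with term column names.
#' @param axisMap numeric parcel map defining the axis.
#' @param nBins number of bins (default 20).
#' @param shift shift bin means to non-negative before weighting.
#' @return data.frame with columns term, weightedPosition, rank; the
#'   nBins x terms matrix of bin means is attached as attribute
#'   `binMeans`, and the per-parcel bin assignment as `bins`.
#' @export
binnedTermRanking <- function(termMaps, axisMap, nBins = 20L, shift = TRUE) {
  n <- length(axisMap)
  if (nrow(termMaps) != n) stop("termMaps rows must match the axis map")
  if (is.null(colnames(termMaps)))
    colnames(termMaps) <- sprintf("term_%d", seq_len(ncol(termMaps)))
  ord <- order(axisMap, seq_len(n))
  bins <- integer(n)
  bins[ord] <- ceiling(seq_len(n) * nBins / n)
  binMeans <- apply(termMaps, 2L, function(v)
    vapply(seq_len(nBins), function(b) mean(v[bins == b]), numeric(1)))
  pos <- vapply(seq_len(ncol(termMaps)), function(j) {
    w <- binMeans[, j]
    if (all(termMaps[, j] == 0)) return(NA_real_)
    if (shift) w <- w - min(w)
    if (sum(w) == 0) return(NA_real_)
    sum(seq_len(nBins) * w) / sum(w)
  }, numeric(1))
  terms <- colnames(termMaps)
  rk <- rep(NA_integer_, length(pos))
  ok <- is.finite(pos)
  rk[ok][order(-pos[ok], terms[ok])] <- seq_len(sum(ok))
  out <- data.frame(term = terms, weightedPosition = pos, rank = rk)
  attr(out, "binMeans") <- binMeans
  attr(out, "bins") <- bins
  out
}
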