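#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles of their ranks,
#' `qnorm(rank / (n + 1))`, with average ranks for ties. Applied to every
#' phenotype before the AE fit so that the Gaussian likelihood assumptions
#' hold regardless of the phenotype's raw scale.
#'
#' @param values numeric vector with at least 3 finite values.
#' @return transformed vector; all zeros (with a warning) if the input is
#'   constant.
#' @export
inverseNormalTransform <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("at least 3 finite values are required")
  if (length(unique(values[ok])) == 1L) {
    warning("all values identical; inverse normal transform is degenerate")
    out <- values
    out[ok] <- 0
    return(out)
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm(r / (sum(ok) + 1))
  out
}

#' Covariate design matrix for the AE model
#'
#' Columns: intercept, centered age, sex, centered age squared, centered
#' age x sex — the covariate set estimated jointly inside the ML fit.
#'
#' @param cohort a [TwinCohort] (or pass `age`/`sex` directly to
#'   `buildDesignMatrix`).
#' @return n x 5 numeric matrix.
#' @export
buildDesign <- function(cohort) {
  ped <- pedigree(cohort)
  if (is.null(ped$age) || is.null(ped$sex))
    stop("cohort must provide age and sex covariates")
  buildDesignMatrix(ped$age, ped$sex)
}

#' @rdname buildDesign
#' @param age,sex numeric covariate vectors.
#' @export
buildDesignMatrix <- function(age, sex) {
  a <- age - mean(age)
  cbind(intercept = 1, age = a, sex = as.numeric(sex),
        age2 = a^2, agesex = a * as.numeric(sex))
}

#' Kinship structure of a twin pedigree
#'
#' Families are independent blocks; the genetic correlation is 1 within MZ
#' pairs, 0.5 within DZ pairs, and each singleton is a 1 x 1 block. The
#' genetic correlation is used directly as the kinship matrix K (equivalent
#' to the 2*Phi parameterization).
#'
#' @param ped pedigree data.frame (subject_id, family_id, zygosity).
#' @return list with `single` (indices), `mz`, `dz` (2 x m index matrices).
#' @export
kinshipBlocks <- function(ped) {
  single <- which(ped$zygosity == "singleton")
  pairIdx <- function(z) {
    fams <- unique(ped$family_id[ped$zygosity == z])
    if (!length(fams)) return(matrix(integer(), 2L, 0L))
    vapply(fams, function(f) which(ped$family_id == f), integer(2L))
  }
  list(single = single, mz = pairIdx("MZ"), dz = pairIdx("DZ"))
}

## Profile log-likelihood of the AE model at a fixed h2: beta by GLS,
## sigma2p by its ML closed form. V is block diagonal with 2x2 pair blocks
## [[1, a], [a, 1]], a = h2 * rg, inverted analytically.
aeProfile <- function(h2, y, X, kb) {
  n <- length(y); p <- ncol(X)
  A <- matrix(0, p, p); b <- numeric(p); yy <- 0; logdet <- 0
  if (length(kb$single)) {
    Xs <- X[kb$single, , drop = FALSE]; ys <- y[kb$single]
    A <- A + crossprod(Xs); b <- b + crossprod(Xs, ys); yy <- yy + sum(ys^2)
  }
  for (grp in list(list(idx = kb$mz, rg = 1), list(idx = kb$dz, rg = 0.5))) {
    m <- ncol(grp$idx)
    if (!m) next
    a <- h2 * grp$rg
    i1 <- grp$idx[1L, ]; i2 <- grp$idx[2L, ]
    X1 <- X[i1, , drop = FALSE]; X2 <- X[i2, , drop = FALSE]
    y1 <- y[i1]; y2 <- y[i2]
    w <- 1 / (1 - a^2)
    A <- A + w * (crossprod(X1) + crossprod(X2) -
                    a * (crossprod(X1, X2) + crossprod(X2, X1)))
    b <- b + w * (crossprod(X1, y1) + crossprod(X2, y2) -
                    a * (crossprod(X1, y2) + crossprod(X2, y1)))
    yy <- yy + w * (sum(y1^2) + sum(y2^2) - 2 * a * sum(y1 * y2))
    logdet <- logdet + m * log(1 - a^2)
  }
  beta <- tryCatch(solve(A, b), error = function(e) MASS::ginv(A) %*% b)
  rss <- as.numeric(yy - 2 * crossprod(beta, b) + t(beta) %*% A %*% beta)
  sigma2p <- max(rss / n, .Machine$double.eps)
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2p) + logdet + n)
  list(loglik = ll, beta = as.numeric(beta), sigma2p = sigma2p)
}

#' Fit the AE twin model by maximum likelihood
#'
#' Maximizes the Gaussian log-likelihood of
#' `y ~ N(X beta, sigma2g K + sigma2e I)` block-wise over families, with K
#' the genetic correlation (MZ 1, DZ 0.5). Covariates are profiled out by
#' GLS at each candidate h2 (joint estimation, no pre-residualization).
#' Optimization is over logit(h2) with multiple starts (h2 = 0.1, 0.5,
#' 0.9) plus explicit boundary evaluation; ties go to the highest
#' log-likelihood, then the smallest h2. The p-value tests sigma2g = 0 by a
#' likelihood-ratio test with the boundary half-half chi-square mixture.
#'
#' @param phenotype numeric phenotype vector in pedigree order (already
#'   transformed if desired; [mapHeritability()] applies the inverse normal
#'   transform for you).
#' @param cohort a [TwinCohort].
#' @param kinship optional precomputed [kinshipBlocks()] result.
#' @param design optional precomputed design matrix.
#' @return a [HeritabilityEstimate].
#' @export
fitAE <- function(phenotype, cohort, kinship = NULL, design = NULL) {
  ped <- pedigree(cohort)
  if (any(!is.finite(phenotype)))
    stop("phenotype must be finite")
  kb <- if (is.null(kinship)) kinshipBlocks(ped) else kinship
  nPairs <- ncol(kb$mz) + ncol(kb$dz)
  if (nPairs < 2L)
    stop("heritability is unidentifiable: need at least 2 twin pairs")
  X <- if (is.null(design)) buildDesign(cohort) else design
  y <- as.numeric(phenotype)

  f <- function(h2) aeProfile(h2, y, X, kb)$loglik
  negll <- function(theta) -f(stats::plogis(theta))
  cand <- list(c(h2 = 0, ll = f(0)), c(h2 = 1 - 1e-10, ll = f(1 - 1e-10)))
  for (start in stats::qlogis(c(0.1, 0.5, 0.9))) {
    opt <- tryCatch(
      stats::nlminb(start, negll, lower = -30, upper = 30),
      error = function(e) NULL)
    if (is.null(opt))
      stop("AE optimizer failed to converge from start ", start)
    cand[[length(cand) + 1L]] <- c(h2 = stats::plogis(opt$par),
                                   ll = -opt$objective)
  }
  lls <- vapply(cand, `[[`, numeric(1), "ll")
  h2s <- vapply(cand, `[[`, numeric(1), "h2")
  best <- order(-lls, h2s)[1L]
  h2 <- min(max(h2s[best], 0), 1)
  fit <- aeProfile(h2, y, X, kb)
  ll0 <- cand[[1L]]["ll"]

  lrt <- 2 * (fit$loglik - ll0)
  p <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)

  se <- NA_real_
  h <- 1e-4
  if (h2 > h && h2 < 1 - h) {
    d2 <- (f(h2 + h) - 2 * fit$loglik + f(h2 - h)) / h^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  }
  new("HeritabilityEstimate",
      h2 = h2, sigma2g = h2 * fit$sigma2p, sigma2e = (1 - h2) * fit$sigma2p,
      sigma2p = fit$sigma2p, beta = fit$beta, loglik = fit$loglik,
      p = as.numeric(p), seH2 = se)
}

#' Node- or edge-wise heritability maps
#'
#' Applies the inverse normal transform followed by the AE fit to every
#' phenotype column. Failures in individual phenotypes are flagged as
#' missing entries; the map is never aborted as a whole.
#'
#' @param phenoMatrix subjects x phenotypes numeric matrix in pedigree
#'   order (e.g., from [connectivityPhenotypes()]).
#' @param cohort a [TwinCohort].
#' @return data.frame with columns phenotype, h2, p, se_h2.
#' @export
mapHeritability <- function(phenoMatrix, cohort) {
  if (is.null(colnames(phenoMatrix)))
    colnames(phenoMatrix) <- sprintf("pheno_%d", seq_len(ncol(phenoMatrix)))
  kb <- kinshipBlocks(pedigree(cohort))
  X <- buildDesign(cohort)
  rows <- lapply(seq_len(ncol(phenoMatrix)), function(j) {
    est <- tryCatch(
      fitAE(inverseNormalTransform(phenoMatrix[, j]), cohort,
            kinship = kb, design = X),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(est))
      data.frame(phenotype = colnames(phenoMatrix)[j],
                 h2 = NA_real_, p = NA_real_, se_h2 = NA_real_)
    else
      data.frame(phenotype = colnames(phenoMatrix)[j],
                 h2 = est@h2, p = est@p, se_h2 = est@seH2)
  })
  do.call(rbind, rows)
}

#' Edge phenotypes from subject connectivity matrices
#'
#' Stacks the upper triangle of each subject's connectome into a subjects x
#' edges matrix suitable for [mapHeritability()].
#'
#' @param matrices list of [ConnectivityMatrix] objects, one per subject,
#'   in pedigree order and with identical parcel order.
#' @return subjects x edges matrix with attribute `pairs` (2 x E parcel
#'   index pairs) and `parcelIds`.
#' @export
connectivityPhenotypes <- function(matrices) {
  ids <- parcelIds(matrices[[1]])
  n <- length(ids)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- t(vapply(matrices, function(m) {
    if (!identical(parcelIds(m), ids))
      stop("subject matrices must share the same parcel order")
    m@mat[upper.tri(m@mat)]
  }, numeric(nrow(ut))))
  colnames(out) <- sprintf("%s|%s", ids[ut[, 1]], ids[ut[, 2]])
  attr(out, "pairs") <- t(unname(ut))
  attr(out, "parcelIds") <- ids
  out
}

#' Reshape an edge-wise result back into a symmetric matrix
#'
#' @param values one value per edge, in [connectivityPhenotypes()] order.
#' @param parcelIds parcel identifiers defining the matrix dimension.
#' @return symmetric matrix with zero diagonal.
#' @export
edgeValuesToMatrix <- function(values, parcelIds) {
  n <- length(parcelIds)
  m <- matrix(0, n, n, dimnames = list(parcelIds, parcelIds))
  m[upper.tri(m)] <- values
  m <- m + t(m)
  m
}
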