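#' Generative specification for synthetic cortices and cohorts
#'
#' Bundles the ground-truth parameters of the synthetic-data generator:
#' class-wise quadratic depth-profile curves, noise levels, and the class
#' coupling targets `kappa` that control how strongly each class's
#' functional community covariance mirrors its microstructural similarity.
#'
#' Class mean profiles are quadratic in depth fraction `d` (0 = outer, 1 =
#' inner): `a + b d + c d^2`, with class-specific `(a, b, c)`. Heavily
#' myelinated idiotypic cortex gets a high, steeply declining profile;
#' paralimbic cortex a low, flat one. Two stable random depth signatures
#' are layered on top: one shared by all parcels of a class
#' (`classEffectSd`, laminar features of the cytoarchitectural type beyond
#' its mean curve, making within-class profiles reliably more alike than
#' between-class ones) and one specific to each parcel (`parcelEffectSd`,
#' giving within-class microstructural similarity a genuine graded pattern
#' for the functional blend to follow).
#'
#' @param verticesPerParcel vertices simulated per parcel.
#' @param nDepths number of intracortical surfaces (>= 2).
#' @param classCurves 4 x 3 matrix of (intercept, slope, curvature) rows in
#'   class order idiotypic, unimodal, heteromodal, paralimbic.
#' @param vertexNoiseSd,subjectNoiseSd,parcelEffectSd,classEffectSd
#'   non-negative noise standard deviations (intensity units) for per-vertex
#'   measurement noise, per-subject curve shifts, stable per-parcel depth
#'   perturbations, and a stable class-level depth signature shared by all
#'   parcels of a class (shared laminar features beyond the mean curve).
#' @param kappa named numeric in \[0,1\] per class: weight of the
#'   microstructure-derived similarity in the functional covariance blend.
#' @param tsLength timepoints per simulated scan (>= 50).
#' @param tsNoiseSd white measurement noise added to the timeseries.
#' @param seed master seed; every operation derives a named substream.
#' @return a `GenerativeSpec` object.
#' @export
generativeSpec <- function(verticesPerParcel = 10L,
                           nDepths = 12L,
                           classCurves = rbind(
                             idiotypic   = c(1.60, -0.80,  0.25),
                             unimodal    = c(1.35, -0.50,  0.10),
                             heteromodal = c(1.20, -0.30, -0.10),
                             paralimbic  = c(1.05, -0.10, -0.30)),
                           vertexNoiseSd = 0.05,
                           subjectNoiseSd = 0.02,
                           parcelEffectSd = 0.15,
                           classEffectSd = 0.08,
                           kappa = c(idiotypic = 0.9, unimodal = 0.5,
                                     heteromodal = 0.1, paralimbic = 0.1),
                           tsLength = 600L,
                           tsNoiseSd = 0.2,
                           seed = 1L) {
  new("GenerativeSpec",
      verticesPerParcel = as.integer(verticesPerParcel),
      nDepths = as.integer(nDepths),
      classCurves = classCurves,
      vertexNoiseSd = vertexNoiseSd, subjectNoiseSd = subjectNoiseSd,
      parcelEffectSd = parcelEffectSd, classEffectSd = classEffectSd,
      kappa = kappa[CLASS_LEVELS],
      tsLength = as.integer(tsLength), tsNoiseSd = tsNoiseSd,
      seed = as.integer(seed))
}

#' @rdname generativeSpec
#' @exportClass GenerativeSpec
setClass("GenerativeSpec",
  representation(
    verticesPerParcel = "integer", nDepths = "integer",
    classCurves = "matrix",
    vertexNoiseSd = "numeric", subjectNoiseSd = "numeric",
    parcelEffectSd = "numeric", classEffectSd = "numeric",
    kappa = "numeric",
    tsLength = "integer", tsNoiseSd = "numeric", seed = "integer"
  )
)

setValidity("GenerativeSpec", function(object) {
  msg <- character()
  if (object@nDepths < 2L) msg <- c(msg, "nDepths must be >= 2")
  if (any(c(object@vertexNoiseSd, object@subjectNoiseSd,
            object@parcelEffectSd, object@classEffectSd,
            object@tsNoiseSd) < 0))
    msg <- c(msg, "all noise sds must be non-negative")
  if (any(object@kappa < 0 | object@kappa > 1) ||
      !identical(names(object@kappa), CLASS_LEVELS))
    msg <- c(msg, "kappa must lie in [0,1] and be named by the four classes")
  if (!identical(dim(object@classCurves), c(4L, 3L)))
    msg <- c(msg, "classCurves must be a 4 x 3 coefficient matrix")
  if (object@tsLength < 50L) msg <- c(msg, "tsLength must be >= 50")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("$", "GenerativeSpec", function(x, name) slot(x, name))

#' Build a toy cortex
#'
#' Places `nParcels` centroids on the unit sphere with a Fibonacci lattice,
#' splits hemispheres by the sign of the x coordinate, assigns one quarter
#' of parcels to each cytoarchitectural class (contiguous blocks along the
#' lattice, giving each class spatial coherence), and simulates per-vertex
#' inner/outer local surface areas with outer > inner (a gyral-crown-like
#' default thickness model).
#'
#' @param nParcels number of parcels; >= 8 and divisible by 4.
#' @param seed integer seed (deterministic output).
#' @param verticesPerParcel vertices per parcel.
#' @return a [ToyCortex].
#' @export
makeToyCortex <- function(nParcels, seed, verticesPerParcel = 10L) {
  if (nParcels < 8L || nParcels %% 4L != 0L)
    stop("nParcels must be >= 8 and divisible by 4")
  k <- seq_len(nParcels) - 0.5
  phi <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * k / nParcels
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- 2 * pi * k / phi
  cen <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  cen <- cen / sqrt(rowSums(cen^2))
  hemi <- factor(ifelse(cen[, 1] < 0, "L", "R"), levels = c("L", "R"))
  cls <- factor(rep(CLASS_LEVELS, each = nParcels / 4L), levels = CLASS_LEVELS)
  atlas <- new("ParcelAtlas",
               parcelIds = sprintf("parcel_%03d", seq_len(nParcels)),
               classLabel = cls, centroid = cen, hemisphere = hemi)
  nv <- nParcels * verticesPerParcel
  areas <- withSubstream(seed, "toy-cortex-areas", {
    inner <- exp(rnorm(nv, mean = log(0.6), sd = 0.15))
    gyral <- 1 + runif(nv, 0.1, 0.6)
    list(inner = inner, outer = inner * gyral)
  })
  new("ToyCortex", atlas = atlas,
      vertexParcel = rep(seq_len(nParcels), each = verticesPerParcel),
      innerArea = areas$inner, outerArea = areas$outer)
}

## Stable per-parcel depth-effect curves: each parcel carries a random
## perturbation defined at the depth-grid knots (interpolated at arbitrary
## depths). Drawn from the spec seed only, so profiles and timeseries agree
## on the same ground truth.
parcelDepthEffects <- function(cortex, spec) {
  nP <- nParcels(cortex)
  cls <- as.integer(cortex@atlas@classLabel)
  classEff <- withSubstream(spec@seed, "class-effects",
    matrix(rnorm(4L * spec@nDepths, sd = spec@classEffectSd),
           4L, spec@nDepths))
  parcelEff <- withSubstream(spec@seed, "parcel-effects",
    matrix(rnorm(nP * spec@nDepths, sd = spec@parcelEffectSd),
           nP, spec@nDepths))
  classEff[cls, , drop = FALSE] + parcelEff
}

## Noiseless expected profile of one parcel's vertex at depths d:
## class quadratic curve plus the interpolated parcel effect.
parcelCurveAt <- function(coefs, effectKnots, knotDepths, d) {
  coefs[1] + coefs[2] * d + coefs[3] * d^2 +
    stats::approx(knotDepths, effectKnots, xout = d, rule = 2)$y
}

## Noiseless parcel profiles at the equivolumetric depths, averaged over
## each parcel's vertices (ground truth for the functional blend).
expectedParcelProfiles <- function(cortex, spec) {
  alpha <- fractionGrid(spec@nDepths)
  rho <- vapply(alpha, function(a)
    equivolumetricFraction(cortex@innerArea, cortex@outerArea, a),
    numeric(length(cortex@innerArea)))
  cls <- as.integer(cortex@atlas@classLabel)
  eff <- parcelDepthEffects(cortex, spec)
  nP <- nParcels(cortex)
  out <- matrix(NA_real_, nP, spec@nDepths)
  for (p in seq_len(nP)) {
    idx <- which(cortex@vertexParcel == p)
    d <- rho[idx, , drop = FALSE]
    vals <- parcelCurveAt(spec@classCurves[cls[p], ], eff[p, ], alpha, as.numeric(d))
    out[p, ] <- colMeans(matrix(vals, nrow = length(idx)))
  }
  rownames(out) <- parcelIds(cortex)
  out
}

#' Simulate depth-wise intensity profiles for a cohort
#'
#' Each vertex's profile is its parcel's quadratic curve evaluated at the
#' vertex's equivolumetric depth fractions, plus a per-subject random shift
#' of intercept and slope and iid per-vertex measurement noise.
#'
#' @param cortex a [ToyCortex].
#' @param spec a `GenerativeSpec`.
#' @param nSubjects number of subjects.
#' @return list with `profiles` (vertices x depths x subjects array),
#'   `fractions` (vertices x depths equivolumetric fractions) and
#'   `vertexParcel`.
#' @export
simulateDepthProfiles <- function(cortex, spec, nSubjects) {
  alpha <- fractionGrid(spec@nDepths)
  rho <- vapply(alpha, function(a)
    equivolumetricFraction(cortex@innerArea, cortex@outerArea, a),
    numeric(length(cortex@innerArea)))
  cls <- as.integer(cortex@atlas@classLabel)
  eff <- parcelDepthEffects(cortex, spec)
  nv <- nrow(rho); nd <- ncol(rho)
  base <- matrix(NA_real_, nv, nd)
  for (v in seq_len(nv)) {
    p <- cortex@vertexParcel[v]
    base[v, ] <- parcelCurveAt(spec@classCurves[cls[p], ], eff[p, ],
                               alpha, rho[v, ])
  }
  arr <- withSubstream(spec@seed, "depth-profiles", {
    out <- array(NA_real_, c(nv, nd, nSubjects))
    for (s in seq_len(nSubjects)) {
      shift <- rnorm(2L, sd = spec@subjectNoiseSd)   # intercept, slope
      out[, , s] <- base + shift[1] + shift[2] * rho +
        matrix(rnorm(nv * nd, sd = spec@vertexNoiseSd), nv, nd)
    }
    out
  })
  list(profiles = arr, fractions = rho, vertexParcel = cortex@vertexParcel)
}

#' Population microstructural similarity of a toy cortex
#'
#' The partial correlation of the noiseless parcel profiles controlling for
#' the cortex-wide mean profile — the population quantity the MPC estimator
#' targets, and the similarity the functional covariance blend follows.
#' (Raw profile correlations are dominated by the shared depth-wise decline
#' and are nearly rank one; the partial correlation carries the graded
#' parcel-level pattern.)
#'
#' @param cortex a [ToyCortex].
#' @param spec a `GenerativeSpec`.
#' @return parcels x parcels similarity matrix with unit diagonal.
#' @export
populationSimilarity <- function(cortex, spec) {
  P <- expectedParcelProfiles(cortex, spec)
  cprof <- colMeans(P)
  rij <- stats::cor(t(P))
  ric <- as.numeric(stats::cor(t(P), cprof))
  S <- (rij - outer(ric, ric)) / sqrt(outer(1 - ric^2, 1 - ric^2))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

## Ground-truth correlation target for the BOLD covariance: per class block
## kappa_c * microstructural similarity + (1 - kappa_c) * an independent
## two-community structure; across classes the similarity damped by
## kappa_i * kappa_j; unit diagonal.
blendedCovariance <- function(cortex, spec) {
  S <- populationSimilarity(cortex, spec)
  nP <- nParcels(cortex)
  cls <- cortex@atlas@classLabel
  comm <- withSubstream(spec@seed, "communities", {
    g <- integer(nP)
    for (cl in CLASS_LEVELS) {
      idx <- which(cls == cl)
      g[idx] <- sample(rep(1:2, length.out = length(idx)))
    }
    g
  })
  ## cross-class covariance follows the microstructural similarity damped
  ## by kappa_i * kappa_j: for a low-coupling class the cross-class signal
  ## drops below the finite-scan sampling noise of the correlation
  ## estimate, which is what erodes its rank-based coupling downstream
  kvec <- spec@kappa[as.character(cls)]
  sigma <- outer(kvec, kvec) * S
  for (cl in CLASS_LEVELS) {
    idx <- which(cls == cl)
    k <- spec@kappa[[cl]]
    commBlock <- ifelse(outer(comm[idx], comm[idx], "=="), 0.5, 0.0)
    diag(commBlock) <- 1
    blk <- k * S[idx, idx] + (1 - k) * commBlock
    diag(blk) <- 1
    sigma[idx, idx] <- blk
  }
  regularizePD(sigma)
}

regularizePD <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  if (lo < 1e-8) {
    load <- 1e-8 - lo + 1e-8
    message(sprintf("blend covariance regularized by diagonal loading %.3g", load))
    sigma <- sigma + diag(load, nrow(sigma))
  }
  sigma
}

#' Simulate community-structured BOLD-like timeseries
#'
#' Draws each subject's timeseries from a zero-mean multivariate normal
#' whose correlation is, per cytoarchitectural class block, the convex blend
#' `kappa_c * (microstructural similarity) + (1 - kappa_c) * (independent
#' two-community structure)`; across classes the correlation follows the
#' microstructural similarity damped by `kappa_i * kappa_j`. Iid white
#' measurement noise is added on top. A non-positive-definite blend is repaired by
#' diagonal loading (reported via `message()`). Supplying `target` replaces
#' the block construction with an explicit full-cortex correlation matrix —
#' useful for building functional data from exactly the same generative
#' similarity as the microstructure.
#'
#' @param cortex a [ToyCortex].
#' @param spec a `GenerativeSpec` (uses `tsLength`, `tsNoiseSd`, `kappa`).
#' @param nSubjects number of subjects.
#' @param target optional parcels x parcels correlation matrix overriding
#'   the class-block blend.
#' @return list of `nSubjects` timepoints x parcels matrices.
#' @export
simulateTimeseries <- function(cortex, spec, nSubjects, target = NULL) {
  if (spec@tsLength < 50L) stop("timeseries length must be >= 50")
  sigma <- if (is.null(target)) blendedCovariance(cortex, spec)
           else regularizePD(target)
  cf <- chol(sigma)
  nP <- nParcels(cortex); TT <- spec@tsLength
  withSubstream(spec@seed, "timeseries", {
    lapply(seq_len(nSubjects), function(s) {
      y <- matrix(rnorm(TT * nP), TT, nP) %*% cf +
        matrix(rnorm(TT * nP, sd = spec@tsNoiseSd), TT, nP)
      colnames(y) <- parcelIds(cortex)
      y
    })
  })
}

#' Simulate a twin cohort under the additive-genetic (AE) model
#'
#' Phenotypes follow `y = X beta + g + e` with `Var(g) = h2 * sigma2p`,
#' `Var(e) = (1 - h2) * sigma2p` (total variance 1), and genetic correlation
#' 1 within MZ pairs, 0.5 within DZ pairs, 0 otherwise. Covariate effects
#' are linear in the design of [buildDesign()] (intercept, centered age,
#' sex, age squared, age x sex). Ages are uniform on 22-36 years and sex is
#' balanced, mirroring a young-adult twin sample.
#'
#' @param nMzPairs,nDzPairs,nSingletons family structure counts.
#' @param h2True true narrow-sense heritability in \[0,1\]; a vector
#'   produces one phenotype column per element.
#' @param covariateBetas length-5 coefficient vector for the design columns;
#'   default small, realistic age/sex effects.
#' @param seed integer seed.
#' @return a [TwinCohort].
#' @export
simulateTwinCohort <- function(nMzPairs, nDzPairs, nSingletons, h2True,
                               covariateBetas = c(0, 0.02, 0.25, 0.001, 0.01),
                               seed = 1L) {
  if (any(h2True < 0 | h2True > 1))
    stop("h2True must lie in [0, 1]")
  if (length(covariateBetas) != 5L)
    stop("covariateBetas must have length 5")
  n <- 2L * nMzPairs + 2L * nDzPairs + nSingletons
  zyg <- c(rep("MZ", 2L * nMzPairs), rep("DZ", 2L * nDzPairs),
           rep("singleton", nSingletons))
  fam <- c(rep(seq_len(nMzPairs), each = 2L),
           if (nDzPairs) nMzPairs + rep(seq_len(nDzPairs), each = 2L),
           if (nSingletons) nMzPairs + nDzPairs + seq_len(nSingletons))
  ped <- withSubstream(seed, "pedigree", {
    famAge <- runif(max(fam), 22, 36)      # twins share their family age
    data.frame(
      subject_id = sprintf("sub_%04d", seq_len(n)),
      family_id = sprintf("fam_%04d", fam),
      zygosity = zyg,
      age = famAge[fam],
      sex = sample(0:1, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  X <- buildDesignMatrix(ped$age, ped$sex)
  pairFirst <- which(zyg != "singleton" & seq_len(n) %% 2L == 1L)
  rg <- ifelse(zyg == "MZ", 1, 0.5)
  ph <- withSubstream(seed, "phenotypes", {
    vapply(seq_along(h2True), function(j) {
      h2 <- h2True[j]
      g <- rnorm(n, sd = sqrt(h2))
      for (i in pairFirst) {    # correlate pair member 2 with member 1
        r <- rg[i]
        g[i + 1L] <- r * g[i] + sqrt(1 - r^2) * rnorm(1L, sd = sqrt(h2))
      }
      e <- rnorm(n, sd = sqrt(1 - h2))
      as.numeric(X %*% covariateBetas) + g + e
    }, numeric(n))
  })
  colnames(ph) <- if (length(h2True) == 1L) "phenotype"
                  else sprintf("phenotype_%d", seq_along(h2True))
  new("TwinCohort", pedigree = ped, phenotypes = ph)
}
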