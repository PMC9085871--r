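#' Run the synthetic structure-function coupling pipeline end to end
#'
#' Generates a toy cortex, simulates depth profiles and BOLD-like
#' timeseries for a cohort, builds subject and group MPC and Fisher-z FC
#' connectomes, and computes the node-wise structure-function coupling map
#' with its class summary. This is the full analysis path a real study
#' would run on parcellated imaging data, exercised on data with known
#' generative class coupling.
#'
#' @param nParcels number of parcels (>= 8, divisible by 4).
#' @param nSubjects number of simulated subjects.
#' @param seed master seed.
#' @param spec a `GenerativeSpec`; defaults to [generativeSpec()] with the
#'   given seed.
#' @return list with `cortex`, `mpc` and `fc` group [ConnectivityMatrix]
#'   objects, the `coupling` parcel map, its `classSummary`, and the
#'   subject-level matrices (`mpcSubjects`, `fcSubjects`).
#' @export
runCouplingPipeline <- function(nParcels = 80L, nSubjects = 10L, seed = 1L,
                                spec = generativeSpec(seed = seed)) {
  cortex <- makeToyCortex(nParcels, seed = spec@seed,
                          verticesPerParcel = spec@verticesPerParcel)
  prof <- simulateDepthProfiles(cortex, spec, nSubjects)
  ids <- parcelIds(cortex)
  mpcSubj <- lapply(seq_len(nSubjects), function(s) {
    pm <- parcelMeanProfiles(prof$profiles[, , s], prof$vertexParcel,
                             nParcels = nParcels, parcelIds = ids)
    mpcSubject(pm, subject = sprintf("sub_%03d", s))
  })
  mpcG <- mpcGroup(mpcSubj)
  ts <- simulateTimeseries(cortex, spec, nSubjects)
  fcSubj <- lapply(seq_len(nSubjects), function(s)
    fcSubject(ts[[s]], subject = sprintf("sub_%03d", s)))
  fcG <- fcGroup(fcSubj)
  coupling <- rowwiseCoupling(mpcG, fcG)
  list(cortex = cortex, mpc = mpcG, fc = fcG,
       mpcSubjects = mpcSubj, fcSubjects = fcSubj,
       coupling = coupling,
       classSummary = classSummary(coupling, cortex@atlas))
}

#' Gradient analysis of a matched MPC/FC pair
#'
#' Computes diffusion-map gradients of both connectomes (row threshold,
#' normalized-angle kernel, alpha = 0.5, multiscale t = 0), Procrustes-
#' aligns the MPC gradients to the FC reference, and returns the
#' gradient-difference map of the principal components.
#'
#' @param mpc,fc group-mean [ConnectivityMatrix] objects.
#' @param atlas a [ParcelAtlas] (sign orientation of the difference map).
#' @param nComponents components to embed (default 10).
#' @param referenceFC if TRUE (default) FC is the Procrustes reference;
#'   otherwise MPC.
#' @inheritParams connectomeGradients
#' @return list with `gMpc`, `gFc` (aligned [GradientSet]s) and `delta`
#'   (the parcel map `z(FC G1) - z(MPC G1)`).
#' @export
gradientPipeline <- function(mpc, fc, atlas, pct = 90, alpha = 0.5, t = 0,
                             nComponents = 10L, referenceFC = TRUE) {
  gMpc <- connectomeGradients(mpc, pct = pct, alpha = alpha, t = t,
                              nComponents = nComponents)
  gFc <- connectomeGradients(fc, pct = pct, alpha = alpha, t = t,
                             nComponents = nComponents)
  if (referenceFC) gMpc <- procrustesAlign(gMpc, gFc)
  else gFc <- procrustesAlign(gFc, gMpc)
  list(gMpc = gMpc, gFc = gFc,
       delta = gradientDifference(gMpc, gFc, component = 1L, atlas = atlas))
}
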