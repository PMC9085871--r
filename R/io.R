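#' Read and write couplemap objects as delimited text
#'
#' All on-disk formats are plain text: atlases and parcel maps as CSV,
#' connectivity matrices as TSV with a parcel-ID header row and column,
#' pedigrees as CSV. Parcel order on disk is the canonical atlas order.
#'
#' @param atlas a [ParcelAtlas].
#' @param path file path.
#' @name couplemap-io
NULL

#' @rdname couplemap-io
#' @export
writeParcelAtlas <- function(atlas, path) {
  cen <- centroids(atlas)
  df <- data.frame(parcel_id = parcelIds(atlas),
                   class = as.character(classLabels(atlas)),
                   hemi = as.character(hemispheres(atlas)),
                   x = cen[, 1], y = cen[, 2], z = cen[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname couplemap-io
#' @export
readParcelAtlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("ParcelAtlas",
      parcelIds = as.character(df$parcel_id),
      classLabel = factor(df$class, levels = CLASS_LEVELS),
      centroid = as.matrix(df[, c("x", "y", "z")]),
      hemisphere = factor(df$hemi, levels = c("L", "R")))
}

#' @rdname couplemap-io
#' @param conn a [ConnectivityMatrix].
#' @export
writeConnectivityMatrix <- function(conn, path) {
  m <- connMatrix(conn)
  df <- data.frame(parcel_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname couplemap-io
#' @param kind connectivity kind for the object read back ("MPC"/"FC_z").
#' @param subject subject label for the object read back.
#' @export
readConnectivityMatrix <- function(path, kind, subject = "group-mean") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  ids <- as.character(df$parcel_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  new("ConnectivityMatrix", mat = m, kind = kind,
      subject = subject, parcelIds = ids)
}

#' @rdname couplemap-io
#' @param map named numeric parcel map.
#' @export
writeParcelMap <- function(map, path) {
  utils::write.csv(data.frame(parcel_id = names(map), value = as.numeric(map)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname couplemap-io
#' @export
readParcelMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  setNames(df$value, df$parcel_id)
}

#' @rdname couplemap-io
#' @param cohort a [TwinCohort].
#' @export
writePedigree <- function(cohort, path) {
  utils::write.csv(pedigree(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname couplemap-io
#' @param phenotypes subjects x phenotypes matrix to attach to the cohort
#'   read back (default: none).
#' @export
readPedigree <- function(path, phenotypes = NULL) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(phenotypes))
    phenotypes <- matrix(numeric(), nrow = nrow(ped), ncol = 0L)
  new("TwinCohort", pedigree = ped, phenotypes = phenotypes)
}

#' @rdname couplemap-io
#' @param gradients a [GradientSet].
#' @export
writeGradientSet <- function(gradients, path) {
  comp <- gradientComponents(gradients)
  df <- data.frame(parcel_id = parcelIds(gradients), comp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- sub("\\.csv$", "", path)
    jsonlite::write_json(
      list(eigenvalues = gradients@eigenvalues, kind = gradients@kind,
           alignment = gradients@alignment),
      paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
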