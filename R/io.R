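# File interchange: NIfTI-1 volumes with JSON sidecars, YAML relaxation
# tables, CSV per-voxel tables, JSON STEAM sidecars.

#' Write a VoxelMap as NIfTI-1 with a JSON sidecar
#'
#' The affine is stored in the sform; the unit tag (plus any extra
#' parameters) goes into `<path stem>.json`.
#'
#' @param map A [VoxelMap-class].
#' @param path Output path (".nii" or ".nii.gz").
#' @param sidecar Extra named fields for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
writeVoxelMap <- function(map, path, sidecar = list()) {
  stopifnot(is(map, "VoxelMap"))
  img <- RNifti::asNifti(mapValues(map))
  img <- RNifti::`sform<-`(img, structure(map@affine, code = 2L))
  RNifti::writeNifti(img, path)
  meta <- c(list(unit = mapUnit(map)), sidecar)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a VoxelMap from NIfTI-1 (+ JSON sidecar)
#'
#' @param path NIfTI path; the sidecar `<stem>.json` supplies the unit when
#'   present.
#' @param unit Unit tag used when no sidecar exists.
#' @return A [VoxelMap-class].
#' @export
readVoxelMap <- function(path, unit = "a.u.") {
  img <- RNifti::readNifti(path)
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$unit)) unit <- meta$unit
  }
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals), 1L))
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  voxelMap(vals, affine = aff, unit = unit)
}

.sidecarPath <- function(path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' STEAM acquisition JSON sidecar I/O
#'
#' @param acq A [SteamAcquisition-class].
#' @param path JSON path.
#' @return `writeSteamAcquisition`: `path` invisibly;
#'   `readSteamAcquisition`: a [SteamAcquisition-class].
#' @export
writeSteamAcquisition <- function(acq, path) {
  stopifnot(is(acq, "SteamAcquisition"))
  jsonlite::write_json(
    list(amplitude = acq@amplitude, tr = acq@tr, te = acq@te, tm = acq@tm,
         alpha = acq@alpha,
         geometry = list(centerMm = acq@geometry@centerMm,
                         dimsMm = acq@geometry@dimsMm)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSteamAcquisition
#' @export
readSteamAcquisition <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  steamAcquisition(j$amplitude, tr = j$tr, te = j$te, tm = j$tm,
                   alpha = j$alpha,
                   geometry = steamVoxelGeometry(j$geometry$centerMm,
                                                 j$geometry$dimsMm))
}

#' Relaxation table YAML I/O
#'
#' Human-editable serialization of a [RelaxationTable-class].
#'
#' @param table A [RelaxationTable-class].
#' @param path YAML path.
#' @return `writeRelaxationTable`: `path` invisibly; `readRelaxationTable`:
#'   a [RelaxationTable-class].
#' @export
writeRelaxationTable <- function(table, path) {
  stopifnot(is(table, "RelaxationTable"))
  yaml::write_yaml(
    list(water = lapply(seq_len(nrow(table@water)), function(i)
           as.list(table@water[i, ])),
         metabolites = lapply(seq_len(nrow(table@metabolites)), function(i)
           as.list(table@metabolites[i, ])),
         constants = table@constants),
    path)
  invisible(path)
}

#' @rdname writeRelaxationTable
#' @export
readRelaxationTable <- function(path) {
  y <- yaml::read_yaml(path)
  new("RelaxationTable",
      water = do.call(rbind, lapply(y$water, as.data.frame)),
      metabolites = do.call(rbind, lapply(y$metabolites, as.data.frame)),
      constants = y$constants)
}

#' Export an MRSI-grid map as CSV
#'
#' One row per MRSI voxel with 0-based x/y indices, matching the voxel
#' indexing of [MRSIGeometry-class].
#'
#' @param map Matrix or MRSI-grid [VoxelMap-class].
#' @param path CSV path.
#' @param valueName Name of the value column.
#' @return `path`, invisibly.
#' @export
exportMRSICsv <- function(map, path, valueName = "value") {
  m <- if (is(map, "VoxelMap")) mapValues(map)[, , 1] else map
  df <- data.frame(
    xIndex = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    yIndex = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    value = as.vector(m))
  names(df)[3] <- valueName
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
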