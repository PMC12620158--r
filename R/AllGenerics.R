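#' @import methods
NULL

#' Access the value array of a map-like object
#'
#' @param x An object holding voxel values.
#' @return A numeric array.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Access the voxel-to-world affine of a map-like object
#'
#' @param x An object with spatial geometry.
#' @return A 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#' @export
setGeneric("mapAffine", function(x) standardGeneric("mapAffine"))

#' Access the unit tag of a map-like object
#'
#' @param x An object with a unit tag.
#' @return A character scalar, one of "ms", "fraction", "relative", "a.u.",
#'   "mmol/kg", "mmol/L".
#' @export
setGeneric("mapUnit", function(x) standardGeneric("mapUnit"))

#' Nominal voxel volume in mm^3
#'
#' @param x A geometry-bearing object.
#' @return Numeric scalar volume in mm^3.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' World coordinates of voxel centers
#'
#' @param x A geometry-bearing object.
#' @return For grid objects, a list with per-axis center coordinate vectors (mm).
#' @export
setGeneric("voxelCenters", function(x) standardGeneric("voxelCenters"))

#' Per-metabolite molal concentration maps
#'
#' @param x A [ConcentrationResult-class].
#' @return Named list of matrices on the MRSI grid, unit mmol/kg water.
#' @export
setGeneric("molalMaps", function(x) standardGeneric("molalMaps"))

#' Per-metabolite molar concentration maps
#'
#' @param x A [ConcentrationResult-class].
#' @return Named list of matrices on the MRSI grid, unit mmol/L tissue.
#' @export
setGeneric("molarMaps", function(x) standardGeneric("molarMaps"))

#' Validity mask of a result
#'
#' @param x A [ConcentrationResult-class].
#' @return Logical matrix; TRUE where the voxel passed all validity checks.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Method tag of a result
#'
#' @param x A [ConcentrationResult-class].
#' @return Character scalar in \code{c("ref", "ref_qmri", "proposed")}.
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))

#' Provenance record of a result
#'
#' @param x A [ConcentrationResult-class].
#' @return Named list of every constant, factor and flag used to produce x.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Tissue fraction accessors
#'
#' Per-MRSI-voxel volume fractions of gray matter, white matter and CSF.
#'
#' @param x A [TissueFractionMap-class].
#' @return A numeric matrix on the MRSI grid with values in (approximately)
#'   \code{[0, 1]}; PSF-weighted fractions may ring slightly outside.
#' @export
setGeneric("fGM", function(x) standardGeneric("fGM"))

#' @rdname fGM
#' @export
setGeneric("fWM", function(x) standardGeneric("fWM"))

#' @rdname fGM
#' @export
setGeneric("fCSF", function(x) standardGeneric("fCSF"))
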