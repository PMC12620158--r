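.UNITS <- c("ms", "fraction", "relative", "a.u.", "mmol/kg", "mmol/L")

# ---------------------------------------------------------------- VoxelMap ----

#' VoxelMap: a 3D scalar field with world geometry and a unit tag
#'
#' Container for one quantitative map (T1, T2, T2*, B1+, water content,
#' amplitude or concentration). Values live on a regular 3D grid; the affine
#' maps 0-based voxel indices (voxel-center convention) to world coordinates
#' in mm. NaN marks invalid voxels.
#'
#' @slot values 3D numeric array.
#' @slot affine 4x4 voxel-to-world transform (mm), invertible.
#' @slot unit Unit tag, one of "ms", "fraction", "relative", "a.u.",
#'   "mmol/kg", "mmol/L".
#'
#' @seealso [voxelMap()], [resliceToMRSI()]
#' @export
setClass("VoxelMap",
  representation(values = "array", affine = "matrix", unit = "character"))

setValidity("VoxelMap", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (any(dim(v) < 1L)) return("each array dimension must be >= 1")
  a <- object@affine
  if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)))
    return("affine must be a 4x4 numeric matrix")
  d <- det(a[1:3, 1:3, drop = FALSE])
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100)
    return("affine must be invertible")
  if (length(object@unit) != 1L || !(object@unit %in% .UNITS))
    return(sprintf("unit must be one of: %s", paste(.UNITS, collapse = ", ")))
  TRUE
})

#' Construct a VoxelMap
#'
#' @param values 3D numeric array (a matrix is promoted to nx x ny x 1).
#' @param affine 4x4 voxel-to-world transform; or NULL to build an axis-aligned
#'   affine from `voxelMm` and `originMm`.
#' @param unit Unit tag (see [VoxelMap-class]).
#' @param voxelMm Length-3 voxel edge lengths in mm (used when affine is NULL).
#' @param originMm World position of the center of voxel (0,0,0)
#'   (used when affine is NULL).
#' @return A [VoxelMap-class] object.
#' @examples
#' vm <- voxelMap(array(0.7, c(8, 8, 4)), unit = "fraction",
#'                voxelMm = c(2.5, 2.5, 2.5), originMm = c(-8.75, -8.75, -3.75))
#' @export
voxelMap <- function(values, affine = NULL, unit = "a.u.",
                     voxelMm = c(1, 1, 1), originMm = c(0, 0, 0)) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (is.null(affine)) affine <- affineFromSpacing(voxelMm, originMm)
  new("VoxelMap", values = values, affine = affine, unit = unit)
}

#' @describeIn voxelMap value array accessor
#' @param x A VoxelMap.
#' @export
setMethod("mapValues", "VoxelMap", function(x) x@values)

#' @describeIn voxelMap affine accessor
#' @export
setMethod("mapAffine", "VoxelMap", function(x) x@affine)

#' @describeIn voxelMap unit accessor
#' @export
setMethod("mapUnit", "VoxelMap", function(x) x@unit)

setMethod("voxelCenters", "VoxelMap", function(x) {
  sp <- affineSpacing(x@affine)
  o <- x@affine[1:3, 4]
  d <- dim(x@values)
  list(x = o[1] + sp[1] * (seq_len(d[1]) - 1),
       y = o[2] + sp[2] * (seq_len(d[2]) - 1),
       z = o[3] + sp[3] * (seq_len(d[3]) - 1))
})

setMethod("show", "VoxelMap", function(object) {
  d <- dim(object@values)
  sp <- tryCatch(affineSpacing(object@affine), error = function(e) rep(NA, 3))
  cat(sprintf("VoxelMap %dx%dx%d [%s], voxel %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@unit, sp[1], sp[2], sp[3]))
  v <- object@values
  cat(sprintf("  finite: %d/%d, range %.4g..%.4g\n",
              sum(is.finite(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

# ------------------------------------------------------------ MRSIGeometry ----

#' MRSIGeometry: the spectroscopic acquisition grid
#'
#' Describes the 2D phase-encoded MRSI grid (single slice): in-plane field of
#' view, phase-encode matrix, slice thickness, pose, and the k-space averaging
#' scheme which determines the point spread function.
#'
#' @slot fovMm In-plane FOV (mm), length 2.
#' @slot matrixSize Phase-encode matrix, length-2 integer (each >= 2).
#' @slot sliceThicknessMm Slice thickness (mm).
#' @slot pose 4x4 voxel-to-world transform for 0-based MRSI indices (i, j, 0).
#' @slot weighting "uniform" (top-hat k-space window) or "weighted"
#'   (Hamming-weighted phase encoding).
#'
#' @export
setClass("MRSIGeometry",
  representation(fovMm = "numeric", matrixSize = "integer",
                 sliceThicknessMm = "numeric", pose = "matrix",
                 weighting = "character"))

setValidity("MRSIGeometry", function(object) {
  if (length(object@fovMm) != 2L || any(object@fovMm <= 0))
    return("fovMm must be two positive numbers")
  if (length(object@matrixSize) != 2L || any(object@matrixSize < 2L))
    return("matrixSize entries must be >= 2")
  if (length(object@sliceThicknessMm) != 1L || object@sliceThicknessMm <= 0)
    return("sliceThicknessMm must be positive")
  if (!identical(dim(object@pose), c(4L, 4L))) return("pose must be 4x4")
  if (!(object@weighting %in% c("uniform", "weighted")))
    return('weighting must be "uniform" or "weighted"')
  TRUE
})

#' Construct an MRSIGeometry
#'
#' By default the grid is centered on `centerMm` with axes aligned to the
#' world frame; voxel (i, j) center is at
#' `center - fov/2 + (i + 0.5) * fov/matrix`.
#'
#' @param fovMm In-plane FOV in mm (length 2), default 240 x 240.
#' @param matrixSize Phase-encode matrix (length 2), default 20 x 20.
#' @param sliceThicknessMm Slice thickness in mm, default 12.
#' @param centerMm World center of the slab (length 3), default origin.
#' @param weighting "uniform" or "weighted" k-space averaging.
#' @param pose Optional explicit 4x4 pose overriding centerMm.
#' @return An [MRSIGeometry-class].
#' @examples
#' g <- mrsiGeometry()          # 20 x 20 over 240 mm, 12 mm slice
#' voxelVolume(g)               # 12 * 12 * 12 = 1728 mm^3
#' @export
mrsiGeometry <- function(fovMm = c(240, 240), matrixSize = c(20L, 20L),
                         sliceThicknessMm = 12, centerMm = c(0, 0, 0),
                         weighting = c("uniform", "weighted"), pose = NULL) {
  weighting <- match.arg(weighting)
  matrixSize <- as.integer(matrixSize)
  if (is.null(pose)) {
    dx <- fovMm / matrixSize
    origin <- c(centerMm[1:2] - fovMm / 2 + dx / 2, centerMm[3])
    pose <- affineFromSpacing(c(dx, sliceThicknessMm), origin)
  }
  new("MRSIGeometry", fovMm = as.numeric(fovMm), matrixSize = matrixSize,
      sliceThicknessMm = as.numeric(sliceThicknessMm), pose = pose,
      weighting = weighting)
}

#' @describeIn mrsiGeometry nominal voxel volume `prod(fov/matrix) * thickness`
#' @param x An MRSIGeometry.
#' @export
setMethod("voxelVolume", "MRSIGeometry", function(x)
  prod(x@fovMm / x@matrixSize) * x@sliceThicknessMm)

setMethod("voxelCenters", "MRSIGeometry", function(x) {
  o <- x@pose[1:3, 4]
  sp <- affineSpacing(x@pose)
  list(x = o[1] + sp[1] * (seq_len(x@matrixSize[1]) - 1),
       y = o[2] + sp[2] * (seq_len(x@matrixSize[2]) - 1),
       z = o[3])
})

setMethod("show", "MRSIGeometry", function(object) {
  cat(sprintf(
    "MRSIGeometry %dx%d, FOV %g x %g mm, slice %g mm, %s phase encoding\n",
    object@matrixSize[1], object@matrixSize[2], object@fovMm[1],
    object@fovMm[2], object@sliceThicknessMm, object@weighting))
})

# ------------------------------------------------------- SteamVoxelGeometry ----

#' SteamVoxelGeometry: the single-voxel STEAM box
#'
#' @slot centerMm World position of the box center (mm, length 3).
#' @slot dimsMm Edge lengths (mm, length 3); default 10 x 10 x 10.
#' @export
setClass("SteamVoxelGeometry",
  representation(centerMm = "numeric", dimsMm = "numeric"))

setValidity("SteamVoxelGeometry", function(object) {
  if (length(object@centerMm) != 3L) return("centerMm must have length 3")
  if (length(object@dimsMm) != 3L || any(object@dimsMm <= 0))
    return("dimsMm must be three positive lengths")
  TRUE
})

#' Construct a SteamVoxelGeometry
#'
#' @param centerMm Box center in world mm.
#' @param dimsMm Box edge lengths in mm (default 10 mm isotropic).
#' @return A [SteamVoxelGeometry-class].
#' @export
steamVoxelGeometry <- function(centerMm = c(0, 0, 0), dimsMm = c(10, 10, 10)) {
  new("SteamVoxelGeometry", centerMm = as.numeric(centerMm),
      dimsMm = as.numeric(dimsMm))
}

setMethod("voxelVolume", "SteamVoxelGeometry", function(x) prod(x@dimsMm))

setMethod("show", "SteamVoxelGeometry", function(object) {
  cat(sprintf("SteamVoxelGeometry %g x %g x %g mm at (%g, %g, %g)\n",
              object@dimsMm[1], object@dimsMm[2], object@dimsMm[3],
              object@centerMm[1], object@centerMm[2], object@centerMm[3]))
})

# -------------------------------------------------------- TissueFractionMap ----

#' TissueFractionMap: per-MRSI-voxel GM/WM/CSF volume fractions
#'
#' Fractions sum to 1 on valid voxels (within 1e-6). With PSF-weighted
#' averaging individual fractions may ring slightly outside [0, 1]; the sum
#' constraint still holds.
#'
#' @slot fGm,fWm,fCsf Numeric matrices on the MRSI grid.
#' @export
setClass("TissueFractionMap",
  representation(fGm = "matrix", fWm = "matrix", fCsf = "matrix"))

setValidity("TissueFractionMap", function(object) {
  d <- dim(object@fGm)
  if (!identical(dim(object@fWm), d) || !identical(dim(object@fCsf), d))
    return("fGm, fWm, fCsf must share dimensions")
  s <- object@fGm + object@fWm + object@fCsf
  ok <- is.finite(s)
  if (any(ok) && max(abs(s[ok] - 1)) > 1e-6)
    return("fractions must sum to 1 (within 1e-6) on valid voxels")
  TRUE
})

#' Construct a TissueFractionMap
#'
#' @param fGm,fWm,fCsf Matrices of volume fractions on the MRSI grid.
#' @return A [TissueFractionMap-class].
#' @export
tissueFractionMap <- function(fGm, fWm, fCsf)
  new("TissueFractionMap", fGm = fGm, fWm = fWm, fCsf = fCsf)

#' @describeIn tissueFractionMap gray-matter fraction
#' @param x A TissueFractionMap.
#' @export
setMethod("fGM", "TissueFractionMap", function(x) x@fGm)

#' @describeIn tissueFractionMap white-matter fraction
#' @export
setMethod("fWM", "TissueFractionMap", function(x) x@fWm)

#' @describeIn tissueFractionMap CSF fraction
#' @export
setMethod("fCSF", "TissueFractionMap", function(x) x@fCsf)

setMethod("show", "TissueFractionMap", function(object) {
  cat(sprintf("TissueFractionMap %dx%d (mean GM %.2f, WM %.2f, CSF %.2f)\n",
              nrow(object@fGm), ncol(object@fGm),
              mean(object@fGm, na.rm = TRUE), mean(object@fWm, na.rm = TRUE),
              mean(object@fCsf, na.rm = TRUE)))
})

# ---------------------------------------------------------- RelaxationTable ----

#' RelaxationTable: literature relaxation values and physical constants
#'
#' Holds per-compartment water T1/T2 and relative water densities, per-
#' metabolite T1/T2, and the constants used throughout quantification. All
#' values are user-overridable and serializable to YAML; the shipped defaults
#' beyond the WM 59/47 ms pair are editable literature-style assumptions,
#' not measured values.
#'
#' @slot water data.frame with columns compartment ("gm","wm","csf"),
#'   t1 (ms), t2 (ms), density (relative water content, unitless).
#' @slot metabolites data.frame with columns name, t1 (ms), t2 (ms).
#' @slot constants Named list: wmT2LitMs (59), wmT2starLitMs (47),
#'   dCsf (1), rhoW (1 kg/L), waterMolal (mmol/kg).
#' @seealso [defaultRelaxationTable()], [readRelaxationTable()]
#' @export
setClass("RelaxationTable",
  representation(water = "data.frame", metabolites = "data.frame",
                 constants = "list"))

setValidity("RelaxationTable", function(object) {
  w <- object@water
  need <- c("compartment", "t1", "t2", "density")
  if (!all(need %in% names(w))) return("water table needs compartment/t1/t2/density")
  if (any(w$t1 <= 0) || any(w$t2 <= 0)) return("relaxation times must be > 0")
  if (any(w$density <= 0 | w$density > 1.2)) return("densities must be in (0, 1.2]")
  m <- object@metabolites
  if (nrow(m) && (!all(c("name", "t1", "t2") %in% names(m)) ||
                  any(m$t1 <= 0) || any(m$t2 <= 0)))
    return("metabolite table needs name/t1/t2 with positive times")
  k <- object@constants
  need <- c("wmT2LitMs", "wmT2starLitMs", "dCsf", "rhoW", "waterMolal")
  if (!all(need %in% names(k))) return("missing constants")
  if (any(unlist(k[need]) <= 0)) return("constants must be positive")
  TRUE
})

#' Default relaxation table
#'
#' WM literature T2/T2* are 59 ms and 47 ms (the pair defining the constant
#' T2* to T2 calibration factor 59/47). The remaining compartment water values
#' (GM/WM/CSF T1 = 1300/830/4300 ms, T2 = 110/80/500 ms, relative water
#' densities 0.78/0.65/1.00) and the metabolite values are editable
#' literature-style defaults. The water molality constant defaults to
#' 55100 mmol/kg; `waterMolalPreset = "physical"` selects 55510 mmol/kg.
#'
#' @param waterMolalPreset "paper" (55100 mmol/kg) or "physical"
#'   (55510 mmol/kg).
#' @return A [RelaxationTable-class].
#' @examples
#' tab <- defaultRelaxationTable()
#' tab@constants$wmT2LitMs / tab@constants$wmT2starLitMs   # 1.255...
#' @export
defaultRelaxationTable <- function(waterMolalPreset = c("paper", "physical")) {
  waterMolalPreset <- match.arg(waterMolalPreset)
  new("RelaxationTable",
      water = data.frame(
        compartment = c("gm", "wm", "csf"),
        t1 = c(1300, 830, 4300),
        t2 = c(110, 80, 500),
        density = c(0.78, 0.65, 1.00),
        stringsAsFactors = FALSE),
      metabolites = data.frame(
        name = c("tNAA", "tCr", "tCho"),
        t1 = c(1400, 1300, 1150),
        t2 = c(250, 160, 220),
        stringsAsFactors = FALSE),
      constants = list(
        wmT2LitMs = 59, wmT2starLitMs = 47, dCsf = 1, rhoW = 1,
        waterMolal = if (waterMolalPreset == "paper") 55100 else 55510))
}

setMethod("show", "RelaxationTable", function(object) {
  cat("RelaxationTable\n  water compartments:\n")
  print(object@water, row.names = FALSE)
  cat("  metabolites:\n")
  print(object@metabolites, row.names = FALSE)
  cat(sprintf("  constants: WM T2/T2* = %g/%g ms, dCSF = %g, rhoW = %g kg/L, water molality = %g mmol/kg\n",
              object@constants$wmT2LitMs, object@constants$wmT2starLitMs,
              object@constants$dCsf, object@constants$rhoW,
              object@constants$waterMolal))
})

# --------------------------------------------------------- SteamAcquisition ----

#' SteamAcquisition: the single-voxel STEAM water measurement
#'
#' @slot amplitude Fitted unsuppressed water amplitude (a.u., > 0).
#' @slot tr,te,tm Repetition, echo and mixing time (ms);
#'   defaults 10000/20/10.
#' @slot alpha Nominal flip angle in degrees (default 90).
#' @slot geometry The STEAM voxel box ([SteamVoxelGeometry-class]).
#' @export
setClass("SteamAcquisition",
  representation(amplitude = "numeric", tr = "numeric", te = "numeric",
                 tm = "numeric", alpha = "numeric",
                 geometry = "SteamVoxelGeometry"))

setValidity("SteamAcquisition", function(object) {
  if (object@amplitude <= 0) return("amplitude must be > 0")
  if (object@tr <= object@tm + object@te / 2)
    return("tr must exceed tm + te/2")
  if (object@alpha <= 0 || object@alpha >= 180)
    return("alpha must lie in (0, 180) degrees")
  TRUE
})

#' Construct a SteamAcquisition
#'
#' @param amplitude Unsuppressed water amplitude (a.u.).
#' @param tr,te,tm Timing in ms (defaults 10000, 20, 10).
#' @param alpha Nominal flip angle (degrees, default 90).
#' @param geometry A [SteamVoxelGeometry-class].
#' @return A [SteamAcquisition-class].
#' @export
steamAcquisition <- function(amplitude, tr = 10000, te = 20, tm = 10,
                             alpha = 90, geometry = steamVoxelGeometry()) {
  new("SteamAcquisition", amplitude = amplitude, tr = tr, te = te, tm = tm,
      alpha = alpha, geometry = geometry)
}

setMethod("show", "SteamAcquisition", function(object) {
  cat(sprintf(
    "SteamAcquisition amp %.4g a.u., TR/TE/TM %g/%g/%g ms, flip %g deg\n",
    object@amplitude, object@tr, object@te, object@tm, object@alpha))
})

# --------------------------------------------------------- SteamLocalValues ----

#' SteamLocalValues: qMRI values averaged over the STEAM voxel
#'
#' T2 is derived from T2* by the constant WM calibration unless a measured
#' T2 is supplied to [steamLocalValues()].
#'
#' @slot t1Steam,t2starSteam,t2Steam Water relaxation times (ms) in the box.
#' @slot b1Steam Relative transmit field (actual/nominal flip).
#' @slot h2oMeanSteam Mean water-content fraction over the box.
#' @export
setClass("SteamLocalValues",
  representation(t1Steam = "numeric", t2starSteam = "numeric",
                 t2Steam = "numeric", b1Steam = "numeric",
                 h2oMeanSteam = "numeric"))

setValidity("SteamLocalValues", function(object) {
  vals <- c(object@t1Steam, object@t2starSteam, object@t2Steam,
            object@b1Steam, object@h2oMeanSteam)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all STEAM-local values must be finite and > 0")
  TRUE
})

#' Construct SteamLocalValues
#'
#' @param t1Steam,t2starSteam Water T1 and T2* (ms) averaged over the box.
#' @param b1Steam Relative B1+ in the box.
#' @param h2oMeanSteam Mean water-content fraction in the box.
#' @param t2Steam Measured water T2 (ms); if NULL, estimated as
#'   `t2FromT2star(t2starSteam, table)`.
#' @param table A [RelaxationTable-class] supplying the calibration constants.
#' @return A [SteamLocalValues-class].
#' @export
steamLocalValues <- function(t1Steam, t2starSteam, b1Steam, h2oMeanSteam,
                             t2Steam = NULL,
                             table = defaultRelaxationTable()) {
  if (is.null(t2Steam)) t2Steam <- t2FromT2star(t2starSteam, table)
  new("SteamLocalValues", t1Steam = t1Steam, t2starSteam = t2starSteam,
      t2Steam = t2Steam, b1Steam = b1Steam, h2oMeanSteam = h2oMeanSteam)
}

setMethod("show", "SteamLocalValues", function(object) {
  cat(sprintf(
    "SteamLocalValues T1 %.0f ms, T2* %.1f ms, T2 %.1f ms, B1+ %.3f, H2O %.3f\n",
    object@t1Steam, object@t2starSteam, object@t2Steam, object@b1Steam,
    object@h2oMeanSteam))
})

# ---------------------------------------------------- MetaboliteAmplitudeSet ----

#' MetaboliteAmplitudeSet: fitted MRSI metabolite amplitudes
#'
#' Raw amplitude-ratio inputs as produced by a spectral fitter with all
#' fitter-side water/metabolite corrections disabled; every correction is
#' applied downstream by the quantification functions.
#'
#' @slot amplitudes Named list of matrices (a.u.) on the MRSI grid.
#' @slot tr,te Metabolite (sLASER) sequence timing in ms; defaults 2000/40.
#' @export
setClass("MetaboliteAmplitudeSet",
  representation(amplitudes = "list", tr = "numeric", te = "numeric"))

setValidity("MetaboliteAmplitudeSet", function(object) {
  a <- object@amplitudes
  if (!length(a)) return("at least one metabolite map required")
  if (is.null(names(a)) || any(!nzchar(names(a))))
    return("amplitude maps must be named")
  d <- dim(a[[1]])
  for (m in a) {
    if (!is.matrix(m) || !identical(dim(m), d))
      return("all amplitude maps must be matrices on one grid")
    if (any(m[is.finite(m)] < 0)) return("amplitudes must be >= 0 or NaN")
  }
  if (object@tr <= 0 || object@te <= 0) return("tr and te must be > 0")
  TRUE
})

#' Construct a MetaboliteAmplitudeSet
#'
#' @param amplitudes Named list of amplitude matrices on the MRSI grid.
#' @param tr,te sLASER repetition/echo time in ms (defaults 2000, 40).
#' @return A [MetaboliteAmplitudeSet-class].
#' @export
metaboliteAmplitudeSet <- function(amplitudes, tr = 2000, te = 40)
  new("MetaboliteAmplitudeSet", amplitudes = amplitudes, tr = tr, te = te)

setMethod("show", "MetaboliteAmplitudeSet", function(object) {
  d <- dim(object@amplitudes[[1]])
  cat(sprintf("MetaboliteAmplitudeSet %s on %dx%d grid, TR/TE %g/%g ms\n",
              paste(names(object@amplitudes), collapse = ", "),
              d[1], d[2], object@tr, object@te))
})

# ------------------------------------------------------- ConcentrationResult ----

#' ConcentrationResult: per-metabolite concentration maps
#'
#' Molal maps are mmol per kg of (non-CSF) tissue water; molar maps are mmol
#' per L of tissue. The two are linked voxel-wise by
#' `molar = molal * (H2O - fCSF) / (1 - fCSF) * rhoW`.
#'
#' @slot molal,molar Named lists of matrices on the MRSI grid.
#' @slot valid Logical matrix; FALSE where a degenerate-voxel rule fired.
#' @slot method "ref", "ref_qmri" or "proposed".
#' @slot provenance Named list of all constants, factors and flags used.
#' @export
setClass("ConcentrationResult",
  representation(molal = "list", molar = "list", valid = "matrix",
                 method = "character", provenance = "list"))

setValidity("ConcentrationResult", function(object) {
  if (!(object@method %in% c("ref", "ref_qmri", "proposed")))
    return('method must be "ref", "ref_qmri" or "proposed"')
  if (!identical(names(object@molal), names(object@molar)))
    return("molal and molar maps must share metabolite names")
  d <- dim(object@valid)
  for (m in c(object@molal, object@molar))
    if (!identical(dim(m), d)) return("all maps must share the grid")
  TRUE
})

#' @describeIn concentrationResult molal maps accessor
#' @export
setMethod("molalMaps", "ConcentrationResult", function(x) x@molal)

#' @describeIn concentrationResult molar maps accessor
#' @export
setMethod("molarMaps", "ConcentrationResult", function(x) x@molar)

#' @describeIn concentrationResult validity mask accessor
#' @export
setMethod("validMask", "ConcentrationResult", function(x) x@valid)

#' @describeIn concentrationResult method tag accessor
#' @export
setMethod("methodTag", "ConcentrationResult", function(x) x@method)

#' @describeIn concentrationResult provenance accessor
#' @export
setMethod("provenance", "ConcentrationResult", function(x) x@provenance)

#' Construct a ConcentrationResult
#'
#' Low-level constructor; users normally obtain results from
#' [quantifyProposed()], [quantifyRefLiterature()] or [quantifyRefQmri()].
#'
#' @param molal,molar Named lists of concentration matrices.
#' @param valid Logical validity matrix.
#' @param method Method tag.
#' @param provenance Provenance list.
#' @return A [ConcentrationResult-class].
#' @export
concentrationResult <- function(molal, molar, valid, method, provenance = list())
  new("ConcentrationResult", molal = molal, molar = molar, valid = valid,
      method = method, provenance = provenance)

setMethod("show", "ConcentrationResult", function(object) {
  cat(sprintf("ConcentrationResult (%s): %s; %d/%d valid voxels\n",
              object@method, paste(names(object@molal), collapse = ", "),
              sum(object@valid), length(object@valid)))
  for (nm in names(object@molal)) {
    v <- object@molal[[nm]][object@valid]
    cat(sprintf("  %-6s median %.2f mmol/kg (molal), %.2f mmol/L (molar)\n",
                nm, stats::median(v, na.rm = TRUE),
                stats::median(object@molar[[nm]][object@valid], na.rm = TRUE)))
  }
})
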