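# Correction of the single-voxel STEAM water amplitude and synthesis of the
# 2D STEAM-MRSI water reference from the water-content map.

#' STEAM correction factors
#'
#' Computes the four multiplicative factors that turn the measured STEAM
#' water amplitude into a fully relaxed, flip-corrected amplitude on the
#' MRSI voxel-volume scale:
#' \describe{
#'   \item{t1corr}{reciprocal of the STEAM longitudinal steady-state
#'     attenuation `(1 - exp((TE/2 + TM - TR)/T1)) * exp(-TM/T1)`. With
#'     `asPrinted = TRUE` the attenuation itself (a number < 1) is returned
#'     instead of its reciprocal, for comparison.}
#'   \item{t2corr}{`exp(TE/T2)`, undoing transverse decay.}
#'   \item{b1corr}{`sin(alpha) / sin(B1 * alpha)^3` with alpha the nominal
#'     flip angle; `cubedNumerator = TRUE` selects
#'     `sin(alpha)^3 / sin(B1 * alpha)^3` (indistinguishable at the nominal
#'     90 degrees).}
#'   \item{voxelcorr}{nominal MRSI voxel volume / STEAM voxel volume.}
#' }
#'
#' @param acq A [SteamAcquisition-class].
#' @param loc A [SteamLocalValues-class].
#' @param mrsiGeom An [MRSIGeometry-class] (supplies the MRSI voxel volume).
#' @param cubedNumerator Use `sin(alpha)^3` in the numerator of the flip
#'   correction.
#' @param asPrinted Return the longitudinal attenuation instead of its
#'   reciprocal (strict as-printed mode; not recommended for quantification).
#' @return Named list `t1corr`, `t2corr`, `b1corr`, `voxelcorr`, all > 0.
#' @examples
#' acq <- steamAcquisition(1)
#' loc <- steamLocalValues(t1Steam = 1000, t2starSteam = 47, b1Steam = 1,
#'                         h2oMeanSteam = 0.7)
#' steamCorrectionFactors(acq, loc, mrsiGeometry())
#' @export
steamCorrectionFactors <- function(acq, loc, mrsiGeom,
                                   cubedNumerator = FALSE,
                                   asPrinted = FALSE) {
  stopifnot(is(acq, "SteamAcquisition"), is(loc, "SteamLocalValues"),
            is(mrsiGeom, "MRSIGeometry"))
  t1att <- (1 - exp((acq@te / 2 + acq@tm - acq@tr) / loc@t1Steam)) *
    exp(-acq@tm / loc@t1Steam)
  t1corr <- if (asPrinted) t1att else 1 / t1att
  t2corr <- exp(acq@te / loc@t2Steam)
  aRad <- acq@alpha * pi / 180
  eff <- loc@b1Steam * aRad
  if (eff <= 0 || eff >= pi)
    stop("effective flip angle B1 * alpha outside (0, 180) degrees")
  num <- if (cubedNumerator) sin(aRad)^3 else sin(aRad)
  b1corr <- num / sin(eff)^3
  voxelcorr <- voxelVolume(mrsiGeom) / voxelVolume(acq@geometry)
  list(t1corr = t1corr, t2corr = t2corr, b1corr = b1corr,
       voxelcorr = voxelcorr)
}

#' Corrected STEAM water amplitude
#'
#' Multiplies the measured STEAM amplitude by 2 (a stimulated echo refocuses
#' only half the available signal), then by the relaxation, flip-angle and
#' voxel-size corrections of [steamCorrectionFactors()].
#'
#' @inheritParams steamCorrectionFactors
#' @param halfSignal Apply the factor 2 (default TRUE).
#' @param ... Passed to [steamCorrectionFactors()].
#' @return Scalar corrected amplitude; NaN (with a warning) if any factor is
#'   NaN.
#' @export
correctSteamSignal <- function(acq, loc, mrsiGeom, halfSignal = TRUE, ...) {
  fac <- steamCorrectionFactors(acq, loc, mrsiGeom, ...)
  out <- acq@amplitude * (if (halfSignal) 2 else 1) *
    fac$t1corr * fac$t2corr * fac$b1corr * fac$voxelcorr
  if (!is.finite(out)) {
    warning("non-finite STEAM correction factor: ",
            paste(sprintf("%s=%.4g", names(fac), unlist(fac)), collapse = ", "))
    out <- NaN
  }
  attr(out, "factors") <- fac
  out
}

#' Synthesize the STEAM-MRSI water reference
#'
#' Scales the resliced water-content map by the corrected STEAM amplitude
#' divided by the mean water content inside the STEAM voxel, producing a
#' per-MRSI-voxel unsuppressed-water reference that is already corrected for
#' water relaxation. The result is invariant to a global rescaling of the
#' water-content map.
#'
#' @param svCorr Corrected STEAM amplitude (from [correctSteamSignal()]).
#' @param h2oMrsi Water-content [VoxelMap-class] on the MRSI grid (from
#'   [resliceToMRSI()]).
#' @param h2oMeanSteam Mean water-content fraction over the STEAM box (from
#'   [steamRegionMean()]).
#' @return A [VoxelMap-class] water reference (unit "a.u.") on the MRSI grid.
#' @export
synthesizeWaterReference <- function(svCorr, h2oMrsi, h2oMeanSteam) {
  stopifnot(is(h2oMrsi, "VoxelMap"))
  if (!is.finite(h2oMeanSteam) || h2oMeanSteam <= 0)
    stop("mean STEAM-voxel water content must be finite and > 0")
  voxelMap(mapValues(h2oMrsi) * (as.numeric(svCorr) / h2oMeanSteam),
           affine = mapAffine(h2oMrsi), unit = "a.u.")
}

#' Calibration factor K between an acquired MRSI water reference and STEAM
#'
#' When the STEAM voxel lies outside the receive-field-normalized MRSI
#' slice, a residual gain mismatch remains. K is estimated from the purest
#' white-matter MRSI voxel (WM fraction > 0.98): its acquired water signal,
#' corrected for relaxation and normalized by local water content, divided
#' by the corrected STEAM amplitude per unit STEAM-voxel water content.
#' Concentration maps from the synthesized reference are multiplied by K
#' when the correction is enabled.
#'
#' @param mrsiWaterRef Acquired unsuppressed water [VoxelMap-class] on the
#'   MRSI grid.
#' @param fractions A [TissueFractionMap-class].
#' @param h2oMrsi Water-content [VoxelMap-class] on the MRSI grid.
#' @param attenMrsi Water attenuation [VoxelMap-class] on the MRSI grid (the
#'   spin-echo attenuation of the acquired reference, e.g. PSF-averaged from
#'   qMRI maps).
#' @param svCorr Corrected STEAM amplitude.
#' @param h2oMeanSteam Mean water content over the STEAM box.
#' @param threshold Minimum WM fraction (default 0.98).
#' @return Scalar K.
#' @export
kFactor <- function(mrsiWaterRef, fractions, h2oMrsi, attenMrsi, svCorr,
                    h2oMeanSteam, threshold = 0.98) {
  wm <- fWM(fractions)
  cand <- which(is.finite(wm) & wm > threshold)
  if (!length(cand))
    stop("no MRSI voxel with WM fraction > ", threshold,
         "; place the STEAM voxel inside the MRSI slice instead of using K")
  sel <- cand[which.max(wm[cand])]
  sw <- mapValues(mrsiWaterRef)[, , 1][sel]
  att <- mapValues(attenMrsi)[, , 1][sel]
  h2o <- mapValues(h2oMrsi)[, , 1][sel]
  (sw / (att * h2o)) / (as.numeric(svCorr) / h2oMeanSteam)
}

#' Full proposed-method water reference from qMRI maps
#'
#' Convenience pipeline: extracts the STEAM-voxel means of T1, T2*, B1+ and
#' water content from the HR qMRI maps, estimates the STEAM-voxel water T2
#' (constant calibration from T2*, or a measured T2 map when given),
#' corrects the STEAM amplitude, reslices the water-content map into MRSI
#' space and synthesizes the water reference.
#'
#' @param acq A [SteamAcquisition-class].
#' @param t1Hr,t2starHr,b1Hr,h2oHr HR [VoxelMap-class] qMRI maps.
#' @param geom An [MRSIGeometry-class].
#' @param table A [RelaxationTable-class].
#' @param t2Hr Optional measured HR T2 map; if supplied its STEAM-box mean
#'   is used instead of the T2* calibration.
#' @param psf PSF mode passed to [resliceToMRSI()].
#' @param ... Passed to [correctSteamSignal()].
#' @return List with `waterRef` (VoxelMap), `h2oMrsi` (VoxelMap), `svCorr`,
#'   `factors`, `local` ([SteamLocalValues-class]).
#' @export
proposedWaterReference <- function(acq, t1Hr, t2starHr, b1Hr, h2oHr, geom,
                                   table = defaultRelaxationTable(),
                                   t2Hr = NULL, psf = NULL, ...) {
  box <- acq@geometry
  loc <- steamLocalValues(
    t1Steam = as.numeric(steamRegionMean(t1Hr, box)),
    t2starSteam = as.numeric(steamRegionMean(t2starHr, box)),
    b1Steam = as.numeric(steamRegionMean(b1Hr, box)),
    h2oMeanSteam = as.numeric(steamRegionMean(h2oHr, box)),
    t2Steam = if (is.null(t2Hr)) NULL
              else as.numeric(steamRegionMean(t2Hr, box)),
    table = table)
  svCorr <- correctSteamSignal(acq, loc, geom, ...)
  h2oMrsi <- resliceToMRSI(h2oHr, geom, psf = psf)
  list(waterRef = synthesizeWaterReference(svCorr, h2oMrsi, loc@h2oMeanSteam),
       h2oMrsi = h2oMrsi, svCorr = as.numeric(svCorr),
       factors = attr(svCorr, "factors"), local = loc)
}
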