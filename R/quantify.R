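# Metabolite concentration maps by three water-scaling methods:
# - proposed: synthesized STEAM-calibrated water reference (water relaxation
#   already corrected in the reference),
# - ref: acquired water reference, literature-value relaxation correction,
# - ref_qmri: acquired water reference, measured qMRI relaxation correction.

#' Metabolite relaxation correction factor
#'
#' `RM = exp(-TE/T2M) * (1 - exp(-TR/T1M))`, the fraction of the fully
#' relaxed metabolite signal observed by the spin-echo MRSI sequence.
#' Strictly increasing in T2M and TR, decreasing in TE.
#'
#' @param t1m,t2m Metabolite relaxation times (ms, > 0; vectorized).
#' @param tr,te Sequence repetition/echo time (ms).
#' @return RM in (0, 1].
#' @examples
#' metaboliteRelaxationFactor(1400, 200, 2000, 40)   # 0.6225
#' @export
metaboliteRelaxationFactor <- function(t1m, t2m, tr, te) {
  stopifnot(all(t1m > 0), all(t2m > 0), tr > 0, te > 0)
  exp(-te / t2m) * (1 - exp(-tr / t1m))
}

#' CSF molal water fraction
#'
#' Fraction of an MRSI voxel's water mass residing in CSF:
#' `fCSF * dCSF / H2O`. Values at or above 1 (all water is CSF) are flagged
#' invalid; non-positive water content yields NaN.
#'
#' @param fCsf CSF volume fraction in \code{[0, 1]} (vectorized).
#' @param dCsf CSF water density (typically 1).
#' @param h2o Water-content fraction (> 0).
#' @return List with `value` (the fraction) and `valid` (logical; FALSE
#'   where value >= 1 or inputs degenerate).
#' @examples
#' csfWaterFraction(0.2, 1, 0.8)$value   # 0.25
#' @export
csfWaterFraction <- function(fCsf, dCsf, h2o) {
  value <- fCsf * dCsf / h2o
  value[!is.finite(h2o) | h2o <= 0] <- NaN
  valid <- is.finite(value) & value < 1
  list(value = value, valid = valid)
}

#' Convert molal to molar concentrations
#'
#' `molar = molal * (H2O - fCSF) / (1 - fCSF) * rhoW`: rescales moles per kg
#' of tissue water to moles per liter of tissue, excluding CSF from both
#' numerator and denominator. Voxels with fCSF = 1 yield NaN.
#'
#' @param molal Concentration map (matrix) in mmol/kg water.
#' @param h2o Water-content map (matrix or [VoxelMap-class]).
#' @param fCsf CSF volume fraction map (matrix).
#' @param rhoW Density of pure water in kg/L (default 1).
#' @return Matrix in mmol/L tissue.
#' @export
molalToMolar <- function(molal, h2o, fCsf, rhoW = 1) {
  if (is(h2o, "VoxelMap")) h2o <- mapValues(h2o)[, , 1]
  out <- molal * (h2o - fCsf) / (1 - fCsf) * rhoW
  out[fCsf >= 1] <- NaN
  out
}

.asGrid <- function(x) {
  if (is(x, "VoxelMap")) mapValues(x)[, , 1] else x
}

.rmFor <- function(table, names, tr, te) {
  m <- table@metabolites
  miss <- setdiff(names, m$name)
  if (length(miss))
    stop("metabolites missing from the relaxation table: ",
         paste(miss, collapse = ", "))
  rm <- metaboliteRelaxationFactor(m$t1, m$t2, tr, te)
  stats::setNames(rm[match(names, m$name)], names)
}

# shared assembly: molar maps, degenerate-voxel policy, provenance
.assembleResult <- function(molal, h2o, fCsf, fCsfH2o, sw, dCsf, rhoW,
                            method, prov) {
  valid <- is.finite(sw) & sw > 0 &
    is.finite(h2o) & is.finite(fCsf) & fCsf < 0.95 &
    is.finite(fCsfH2o) & fCsfH2o < 1 &
    (h2o - fCsf * dCsf) > 0
  molar <- lapply(molal, molalToMolar, h2o = h2o, fCsf = fCsf, rhoW = rhoW)
  for (nm in names(molal)) valid <- valid & is.finite(molal[[nm]])
  prov$degenerateVoxelPolicy <-
    "fCSF >= 0.95, waterRef <= 0, or (H2O - fCSF*dCSF) <= 0 masked invalid"
  # the water-content and CSF-fraction maps that link molal to molar
  prov$h2oMap <- h2o
  prov$fCsfMap <- fCsf
  prov$rhoW <- rhoW
  concentrationResult(molal, molar, valid, method, prov)
}

#' Quantify metabolites with the synthesized STEAM water reference
#'
#' Divides each metabolite amplitude by the synthesized water reference,
#' corrects CSF partial volume and metabolite relaxation, and scales by the
#' molality of water. No water-relaxation term appears: the synthesized
#' reference is already relaxation-corrected.
#'
#' @param sm A [MetaboliteAmplitudeSet-class].
#' @param waterRef Synthesized water reference ([VoxelMap-class] or matrix),
#'   see [synthesizeWaterReference()].
#' @param fractions A [TissueFractionMap-class]. For exact consistency with
#'   PSF-formed signals, pass PSF-weighted fractions
#'   (`tissueFractionsToMRSI(..., psf = TRUE)`).
#' @param h2oMrsi Water-content map on the MRSI grid.
#' @param table A [RelaxationTable-class].
#' @param k Optional gain re-calibration factor (see [kFactor()]); default 1.
#' @return A [ConcentrationResult-class] with method tag "proposed".
#' @export
quantifyProposed <- function(sm, waterRef, fractions, h2oMrsi,
                             table = defaultRelaxationTable(), k = 1) {
  stopifnot(is(sm, "MetaboliteAmplitudeSet"), is(fractions, "TissueFractionMap"))
  sw <- .asGrid(waterRef)
  h2o <- .asGrid(h2oMrsi)
  fCsf <- fCSF(fractions)
  kc <- table@constants
  cw <- csfWaterFraction(fCsf, kc$dCsf, h2o)
  rms <- .rmFor(table, names(sm@amplitudes), sm@tr, sm@te)
  molal <- lapply(names(sm@amplitudes), function(nm)
    sm@amplitudes[[nm]] / sw / (1 - cw$value) / rms[[nm]] * kc$waterMolal * k)
  names(molal) <- names(sm@amplitudes)
  .assembleResult(molal, h2o, fCsf, cw$value, sw, kc$dCsf, kc$rhoW,
                  "proposed",
                  list(waterMolal = kc$waterMolal, k = k, rm = rms,
                       tr = sm@tr, te = sm@te, dCsf = kc$dCsf,
                       rhoW = kc$rhoW, waterReference = "synthesized STEAM"))
}

#' Quantify metabolites with literature-value water scaling
#'
#' Conventional compartment water scaling: the acquired unsuppressed water
#' reference is decomposed into GM/WM/CSF molal water fractions
#' `f_c^H2O = f_c * alpha_c / sum_j f_j * alpha_j` (alpha = compartment
#' relative water densities), each attenuated by the literature spin-echo
#' factor [waterAttenuationSE()]. Voxels dominated by CSF (fraction >= 0.95)
#' are flagged unreliable.
#'
#' @param sm A [MetaboliteAmplitudeSet-class].
#' @param sw Acquired unsuppressed MRSI water reference ([VoxelMap-class] or
#'   matrix).
#' @param fractions A [TissueFractionMap-class].
#' @param table A [RelaxationTable-class] supplying the literature values.
#' @return A [ConcentrationResult-class] with method tag "ref".
#' @export
quantifyRefLiterature <- function(sm, sw, fractions,
                                  table = defaultRelaxationTable()) {
  stopifnot(is(sm, "MetaboliteAmplitudeSet"), is(fractions, "TissueFractionMap"))
  swv <- .asGrid(sw)
  w <- table@water
  alpha <- stats::setNames(w$density, w$compartment)
  att <- stats::setNames(waterAttenuationSE(w$t1, w$t2, sm@tr, sm@te),
                         w$compartment)
  f <- list(gm = fGM(fractions), wm = fWM(fractions), csf = fCSF(fractions))
  W <- f$gm * alpha["gm"] + f$wm * alpha["wm"] + f$csf * alpha["csf"]
  attBar <- (f$gm * alpha["gm"] * att["gm"] + f$wm * alpha["wm"] * att["wm"] +
             f$csf * alpha["csf"] * att["csf"]) / W
  fCsfH2o <- f$csf * alpha["csf"] / W
  kc <- table@constants
  rms <- .rmFor(table, names(sm@amplitudes), sm@tr, sm@te)
  molal <- lapply(names(sm@amplitudes), function(nm)
    sm@amplitudes[[nm]] / swv * attBar / (1 - fCsfH2o) / rms[[nm]] *
      kc$waterMolal)
  names(molal) <- names(sm@amplitudes)
  .assembleResult(molal, W, f$csf, fCsfH2o, swv, kc$dCsf, kc$rhoW, "ref",
                  list(waterMolal = kc$waterMolal, rm = rms,
                       tr = sm@tr, te = sm@te,
                       literatureWater = table@water,
                       waterReference = "acquired, literature scaling"))
}

#' Quantify metabolites with qMRI-based water scaling
#'
#' As [quantifyRefLiterature()], but the water attenuation is computed from
#' the measured T1/T2 maps and the CSF molal water fraction from the
#' measured water-content map. By default the attenuation is evaluated per
#' HR voxel and PSF-averaged into the MRSI grid weighted by water content
#' (signal formation is linear in attenuation); `mode = "averaged"`
#' evaluates it at the resliced T1/T2 instead.
#'
#' @param sm A [MetaboliteAmplitudeSet-class].
#' @param sw Acquired unsuppressed MRSI water reference ([VoxelMap-class] or
#'   matrix).
#' @param fractions A [TissueFractionMap-class].
#' @param t1Hr HR T1 [VoxelMap-class] (ms).
#' @param h2oHr HR water-content [VoxelMap-class].
#' @param geom An [MRSIGeometry-class].
#' @param t2Hr HR T2 [VoxelMap-class]; if NULL, estimated from `t2starHr` by
#'   [t2FromT2star()].
#' @param t2starHr HR T2* map, used only when `t2Hr` is NULL.
#' @param table A [RelaxationTable-class].
#' @param mode "hr" (attenuation per HR voxel, then PSF-averaged) or
#'   "averaged" (attenuation at resliced T1/T2).
#' @param psf PSF mode passed to [resliceToMRSI()].
#' @return A [ConcentrationResult-class] with method tag "ref_qmri".
#' @export
quantifyRefQmri <- function(sm, sw, fractions, t1Hr, h2oHr, geom,
                            t2Hr = NULL, t2starHr = NULL,
                            table = defaultRelaxationTable(),
                            mode = c("hr", "averaged"), psf = NULL) {
  stopifnot(is(sm, "MetaboliteAmplitudeSet"), is(fractions, "TissueFractionMap"))
  mode <- match.arg(mode)
  if (is.null(t2Hr)) {
    if (is.null(t2starHr))
      stop("supply a measured T2 map or a T2* map for the constant calibration")
    t2Hr <- voxelMap(t2FromT2star(mapValues(t2starHr), table),
                     affine = mapAffine(t2starHr), unit = "ms")
  }
  swv <- .asGrid(sw)
  h2oM <- .asGrid(resliceToMRSI(h2oHr, geom, psf = psf))
  if (mode == "hr") {
    aHr <- waterAttenuationSE(mapValues(t1Hr), mapValues(t2Hr), sm@tr, sm@te)
    num <- .asGrid(resliceToMRSI(
      voxelMap(mapValues(h2oHr) * aHr, affine = mapAffine(h2oHr),
               unit = "a.u."), geom, psf = psf))
    attBar <- num / h2oM
  } else {
    t1M <- .asGrid(resliceToMRSI(t1Hr, geom, psf = psf))
    t2M <- .asGrid(resliceToMRSI(t2Hr, geom, psf = psf))
    attBar <- waterAttenuationSE(t1M, t2M, sm@tr, sm@te)
  }
  fCsf <- fCSF(fractions)
  kc <- table@constants
  cw <- csfWaterFraction(fCsf, kc$dCsf, h2oM)
  rms <- .rmFor(table, names(sm@amplitudes), sm@tr, sm@te)
  molal <- lapply(names(sm@amplitudes), function(nm)
    sm@amplitudes[[nm]] / swv * attBar / (1 - cw$value) / rms[[nm]] *
      kc$waterMolal)
  names(molal) <- names(sm@amplitudes)
  .assembleResult(molal, h2oM, fCsf, cw$value, swv, kc$dCsf, kc$rhoW,
                  "ref_qmri",
                  list(waterMolal = kc$waterMolal, rm = rms,
                       tr = sm@tr, te = sm@te, attenuationMode = mode,
                       waterReference = "acquired, qMRI scaling"))
}
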