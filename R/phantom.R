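# Seeded synthetic phantom: co-registered HR qMRI maps, segmentation, MRSI
# metabolite/water amplitudes and a STEAM water measurement with known
# ground truth, generated under the same forward model the quantification
# inverts:
#   SW(v)    = g * V * rhoW * H2Omolal * <H2O * A_w(T1,T2)>_PSF
#   SM_m(v)  = g * V * rhoW * RM_m     * <c_m * (H2O - pCSF * dCSF)>_PSF
#   STEAM    = (1/2) * g * Vsteam * rhoW * H2Omolal * <H2O>_box * A_steam
# with A_steam the longitudinal/transverse/flip-angle attenuation of the
# stimulated echo. Noise is multiplicative Gaussian on measured amplitudes.

#' Phantom configuration
#'
#' Defines the simulated anatomy (elliptical WM core, GM background, two
#' CSF pockets, optional rectangular lesion), tissue parameters, true
#' concentrations, acquisition parameters, B1+ field, gain, noise and seed.
#' Tissue relaxation and water-content defaults equal the
#' [defaultRelaxationTable()] literature values, so the literature-scaling
#' method's assumptions hold exactly unless `relaxationScale` departs from
#' 1. With `calibratedWm = TRUE` the WM T2* is set to WM T2 divided by the
#' constant calibration ratio, so the synthesized-reference method's T2
#' estimate is exact in the (WM-placed) STEAM voxel.
#'
#' @param hrMatrix HR grid size, default c(96, 96, 24).
#' @param hrVoxelMm HR voxel size in mm, default 2.5 isotropic.
#' @param mrsiMatrix,fovMm,sliceThicknessMm MRSI grid, default 20 x 20 over
#'   240 mm, 12 mm slice.
#' @param tissue data.frame with compartment ("gm","wm","csf"), t1, t2,
#'   t2star (ms) and h2o (fraction). Defaults mirror the literature table;
#'   CSF water content is 1 (CSF-normalized water-content map).
#' @param calibratedWm Force WM T2* = WM T2 / t2CalibrationRatio.
#' @param t2CalibrationRatio The constant T2/T2* calibration, default 59/47.
#' @param relaxationScale Named multipliers (t1, t2, h2o) applied to GM/WM
#'   truth (CSF kept fixed); T2* is scaled with T2 so a calibrated WM stays
#'   calibrated. Departing from 1 breaks the literature method's
#'   assumptions on purpose.
#' @param concentrations Named true molal concentrations (mmol/kg water).
#' @param lesion NULL or a list with centerMm (length 2), sizeMm (length 2),
#'   t1, t2, t2star, h2o, label ("gm" by default: lesions segment as GM),
#'   concScale (named multipliers).
#' @param gain Global scanner gain.
#' @param noiseSigma Multiplicative Gaussian noise SD on amplitudes.
#' @param steamCenterMm,steamDimsMm STEAM voxel box (default 10 mm cube in
#'   the WM core at x = -45 mm).
#' @param slaserTr,slaserTe,steamTr,steamTe,steamTm,alpha Sequence timing
#'   (ms) and nominal flip (degrees); defaults 2000/40, 10000/20/10, 90.
#' @param b1Center,b1Falloff Smooth transmit field
#'   `B1(r) = b1Center - b1Falloff * (r / (FOV/2))^2`.
#' @param seed RNG seed.
#' @return A list of class "PhantomConfig".
#' @export
phantomConfig <- function(hrMatrix = c(96L, 96L, 24L),
                          hrVoxelMm = c(2.5, 2.5, 2.5),
                          mrsiMatrix = c(20L, 20L),
                          fovMm = c(240, 240),
                          sliceThicknessMm = 12,
                          tissue = NULL,
                          calibratedWm = TRUE,
                          t2CalibrationRatio = 59 / 47,
                          relaxationScale = c(t1 = 1, t2 = 1, h2o = 1),
                          concentrations = c(tNAA = 13.5, tCr = 9.0,
                                             tCho = 2.7),
                          lesion = NULL,
                          gain = 1,
                          noiseSigma = 0,
                          steamCenterMm = c(-45, 0, 0),
                          steamDimsMm = c(10, 10, 10),
                          slaserTr = 2000, slaserTe = 40,
                          steamTr = 10000, steamTe = 20, steamTm = 10,
                          alpha = 90,
                          b1Center = 1.05, b1Falloff = 0.09,
                          seed = 1L) {
  if (is.null(tissue))
    tissue <- data.frame(
      compartment = c("gm", "wm", "csf"),
      t1 = c(1300, 830, 4300),
      t2 = c(110, 80, 500),
      t2star = c(55, 47, 200),
      h2o = c(0.78, 0.65, 1.00),
      stringsAsFactors = FALSE)
  sc <- c(t1 = 1, t2 = 1, h2o = 1)
  sc[names(relaxationScale)] <- relaxationScale
  for (cmp in c("gm", "wm")) {
    i <- tissue$compartment == cmp
    tissue$t1[i] <- tissue$t1[i] * sc[["t1"]]
    tissue$t2[i] <- tissue$t2[i] * sc[["t2"]]
    tissue$t2star[i] <- tissue$t2star[i] * sc[["t2"]]
    tissue$h2o[i] <- pmin(tissue$h2o[i] * sc[["h2o"]], 0.99)
  }
  if (calibratedWm) {
    i <- tissue$compartment == "wm"
    tissue$t2star[i] <- tissue$t2[i] / t2CalibrationRatio
  }
  if (!is.null(lesion)) {
    lesion <- utils::modifyList(
      list(centerMm = c(45, 5), sizeMm = c(30, 30),
           t1 = 1245, t2 = 120, t2star = 120 / t2CalibrationRatio,
           h2o = 0.95, label = "gm",
           concScale = c(tNAA = 0.6, tCr = 0.8, tCho = 1.5)),
      lesion)
    half <- lesion$sizeMm / 2
    if (any(abs(lesion$centerMm) + half > fovMm / 2))
      stop("lesion box extends outside the FOV")
  }
  cfg <- list(hrMatrix = as.integer(hrMatrix), hrVoxelMm = hrVoxelMm,
              mrsiMatrix = as.integer(mrsiMatrix), fovMm = fovMm,
              sliceThicknessMm = sliceThicknessMm, tissue = tissue,
              calibratedWm = calibratedWm,
              t2CalibrationRatio = t2CalibrationRatio,
              concentrations = concentrations, lesion = lesion,
              gain = gain, noiseSigma = noiseSigma,
              steamCenterMm = steamCenterMm, steamDimsMm = steamDimsMm,
              slaserTr = slaserTr, slaserTe = slaserTe, steamTr = steamTr,
              steamTe = steamTe, steamTm = steamTm, alpha = alpha,
              b1Center = b1Center, b1Falloff = b1Falloff,
              seed = as.integer(seed))
  stopifnot(noiseSigma >= 0, gain > 0,
            all(tissue$t1 > 0), all(tissue$t2 > 0), all(tissue$t2star > 0),
            all(tissue$h2o > 0 & tissue$h2o <= 1))
  class(cfg) <- c("PhantomConfig", "list")
  cfg
}

#' Apply multiplicative Gaussian noise to amplitudes
#'
#' `s * (1 + sigma * N(0,1))`, element-wise. With `sigma = 0` the input is
#' returned unchanged.
#'
#' @param signals Numeric vector, matrix or array.
#' @param sigma Noise standard deviation (relative).
#' @param seed Optional seed set before drawing.
#' @return Perturbed signals, same shape.
#' @export
addNoise <- function(signals, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(signals)
  if (!is.null(seed)) set.seed(seed)
  signals * (1 + sigma * stats::rnorm(length(signals)))
}

.insideEllipse <- function(x, y, cx, cy, ax, ay)
  ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1

#' Generate a synthetic phantom data set
#'
#' Builds the HR anatomy and qMRI maps, forms the MRSI metabolite and water
#' amplitudes through the PSF forward model, simulates the STEAM water
#' measurement, applies seeded multiplicative noise, and records every
#' intermediate together with the ground truth. Identical seeds give
#' identical output.
#'
#' @param config A [phantomConfig()] list.
#' @param table A [RelaxationTable-class]; supplies metabolite relaxation
#'   times, dCSF, rhoW and the water molality constant used in the forward
#'   model.
#' @param psf PSF mode for signal formation (default "fourier").
#' @return A list of class "PhantomTruth" with elements `geom`, `maps` (HR
#'   VoxelMaps: t1, t2, t2star, b1, h2o, labels), `probMaps`,
#'   `fractionsPsf`, `fractionsBox`, `h2oMrsi`, `sm`
#'   ([MetaboliteAmplitudeSet-class]), `sw` (acquired-water
#'   [VoxelMap-class]), `steam` ([SteamAcquisition-class]), `truth`
#'   (concentrations, per-voxel molal truth on the HR grid, lesion mask,
#'   noise-free signals, STEAM box means, scale factors), and `config`.
#' @examples
#' ph <- generatePhantom(phantomConfig(noiseSigma = 0, seed = 7))
#' ph$steam
#' @export
generatePhantom <- function(config, table = defaultRelaxationTable(),
                            psf = "fourier") {
  stopifnot(inherits(config, "PhantomConfig"))
  set.seed(config$seed)
  hm <- config$hrMatrix
  sp <- config$hrVoxelMm
  ext <- hm * sp
  orig <- c(-ext[1:2] / 2 + sp[1:2] / 2, -ext[3] / 2 + sp[3] / 2)
  aff <- affineFromSpacing(sp, orig)
  xs <- orig[1] + sp[1] * (seq_len(hm[1]) - 1)
  ys <- orig[2] + sp[2] * (seq_len(hm[2]) - 1)
  X <- matrix(xs, hm[1], hm[2])
  Y <- matrix(ys, hm[1], hm[2], byrow = TRUE)

  # anatomy: WM ellipse core with two CSF pockets, GM elsewhere
  lab2d <- matrix(1L, hm[1], hm[2])                        # 1 = GM
  lab2d[.insideEllipse(X, Y, 0, 0, 80, 65)] <- 2L          # 2 = WM
  lab2d[.insideEllipse(X, Y, 0, 28, 13, 9)] <- 3L          # 3 = CSF
  lab2d[.insideEllipse(X, Y, 0, -28, 13, 9)] <- 3L
  lesionMask2d <- matrix(FALSE, hm[1], hm[2])
  if (!is.null(config$lesion)) {
    le <- config$lesion
    half <- le$sizeMm / 2
    lesionMask2d <- abs(X - le$centerMm[1]) <= half[1] &
      abs(Y - le$centerMm[2]) <= half[2]
    lab2d[lesionMask2d] <- match(le$label, c("gm", "wm", "csf"))
  }

  ts <- config$tissue
  pick <- function(col) {
    v <- ts[[col]][lab2d]
    if (!is.null(config$lesion)) v[lesionMask2d] <- config$lesion[[col]]
    matrix(v, hm[1], hm[2])
  }
  t1_2d <- pick("t1"); t2_2d <- pick("t2")
  t2s_2d <- pick("t2star"); h2o_2d <- pick("h2o")
  r2 <- (X^2 + Y^2) / (min(config$fovMm) / 2)^2
  b1_2d <- config$b1Center - config$b1Falloff * r2

  rep3d <- function(m) array(m, c(hm[1], hm[2], hm[3]))
  mk <- function(m, unit) new("VoxelMap", values = rep3d(m), affine = aff,
                              unit = unit)
  maps <- list(t1 = mk(t1_2d, "ms"), t2 = mk(t2_2d, "ms"),
               t2star = mk(t2s_2d, "ms"), b1 = mk(b1_2d, "relative"),
               h2o = mk(h2o_2d, "fraction"),
               labels = mk(lab2d + 0, "a.u."))
  probMaps <- list(
    gm = mk((lab2d == 1L) + 0, "fraction"),
    wm = mk((lab2d == 2L) + 0, "fraction"),
    csf = mk((lab2d == 3L) + 0, "fraction"))

  geom <- mrsiGeometry(fovMm = config$fovMm, matrixSize = config$mrsiMatrix,
                       sliceThicknessMm = config$sliceThicknessMm)
  fractionsPsf <- tissueFractionsToMRSI(probMaps, geom, psf = psf)
  fractionsBox <- tissueFractionsToMRSI(probMaps, geom, psf = FALSE)
  h2oMrsi <- resliceToMRSI(maps$h2o, geom, psf = psf)

  kc <- table@constants
  V <- voxelVolume(geom)
  g <- config$gain
  wScale <- g * V * kc$rhoW * kc$waterMolal

  # acquired unsuppressed MRSI water: water content times SE attenuation
  aW2d <- waterAttenuationSE(t1_2d, t2_2d, config$slaserTr, config$slaserTe)
  swClean <- wScale *
    mapValues(resliceToMRSI(mk(h2o_2d * aW2d, "a.u."), geom, psf = psf))[, , 1]

  # metabolite amplitudes: concentration times non-CSF water times RM
  pCsf2d <- (lab2d == 3L) + 0
  metWater2d <- h2o_2d - pCsf2d * kc$dCsf
  mets <- names(config$concentrations)
  rms <- .rmFor(table, mets, config$slaserTr, config$slaserTe)
  truthMolalHr <- list()
  smClean <- list()
  for (nm in mets) {
    c2d <- matrix(config$concentrations[[nm]], hm[1], hm[2])
    if (!is.null(config$lesion)) {
      csc <- config$lesion$concScale
      if (!is.null(csc) && nm %in% names(csc))
        c2d[lesionMask2d] <- c2d[lesionMask2d] * csc[[nm]]
    }
    truthMolalHr[[nm]] <- c2d
    smClean[[nm]] <- g * V * kc$rhoW * rms[[nm]] *
      mapValues(resliceToMRSI(mk(c2d * metWater2d, "a.u."), geom,
                              psf = psf))[, , 1]
  }

  # STEAM: box treated as homogeneous at its HR means
  box <- steamVoxelGeometry(config$steamCenterMm, config$steamDimsMm)
  bm <- list(t1 = as.numeric(steamRegionMean(maps$t1, box)),
             t2 = as.numeric(steamRegionMean(maps$t2, box)),
             t2star = as.numeric(steamRegionMean(maps$t2star, box)),
             b1 = as.numeric(steamRegionMean(maps$b1, box)),
             h2o = as.numeric(steamRegionMean(maps$h2o, box)))
  aRad <- config$alpha * pi / 180
  attSteam <- (1 - exp((config$steamTe / 2 + config$steamTm -
                          config$steamTr) / bm$t1)) *
    exp(-config$steamTm / bm$t1) *
    exp(-config$steamTe / bm$t2) *
    sin(bm$b1 * aRad)^3 / sin(aRad)
  ampClean <- 0.5 * g * prod(config$steamDimsMm) * kc$rhoW * kc$waterMolal *
    bm$h2o * attSteam

  # seeded multiplicative noise on measured amplitudes only; Gibbs ringing
  # of the PSF can drive near-edge amplitudes non-positive, where no
  # spectral fit would succeed -> marked invalid (NaN)
  sig <- config$noiseSigma
  sw <- addNoise(swClean, sig)
  smNoisy <- lapply(smClean, function(s) {
    s <- addNoise(s, sig)
    s[s <= 0] <- NaN
    s
  })
  amp <- addNoise(ampClean, sig)

  out <- list(
    geom = geom, maps = maps, probMaps = probMaps,
    fractionsPsf = fractionsPsf, fractionsBox = fractionsBox,
    h2oMrsi = h2oMrsi,
    sm = metaboliteAmplitudeSet(smNoisy, tr = config$slaserTr,
                                te = config$slaserTe),
    sw = voxelMap(sw, affine = mapAffine(h2oMrsi), unit = "a.u."),
    steam = steamAcquisition(amp, tr = config$steamTr, te = config$steamTe,
                             tm = config$steamTm, alpha = config$alpha,
                             geometry = box),
    truth = list(concentrations = config$concentrations,
                 molalHr = truthMolalHr,
                 lesionMaskHr = lesionMask2d,
                 labels2d = lab2d,
                 swClean = swClean, smClean = smClean,
                 steamAmplitudeClean = ampClean,
                 steamBoxMeans = bm, steamAttenuation = attSteam,
                 waterScale = wScale, rm = rms),
    table = table, config = config)
  class(out) <- c("PhantomTruth", "list")
  out
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat(sprintf(
    "PhantomTruth (seed %d): %dx%dx%d HR grid, %dx%d MRSI, noise %.3g\n",
    x$config$seed, x$config$hrMatrix[1], x$config$hrMatrix[2],
    x$config$hrMatrix[3], x$config$mrsiMatrix[1], x$config$mrsiMatrix[2],
    x$config$noiseSigma))
  cat("  metabolites:",
      paste(sprintf("%s=%.3g", names(x$truth$concentrations),
                    x$truth$concentrations), collapse = ", "),
      "mmol/kg\n")
  invisible(x)
}

#' @export
print.PhantomConfig <- function(x, ...) {
  cat(sprintf("PhantomConfig seed %d, noise %.3g, gain %.3g, %s lesion\n",
              x$seed, x$noiseSigma, x$gain,
              if (is.null(x$lesion)) "no" else "with"))
  invisible(x)
}
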