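steamLoc <- function(t1 = 1000, t2star = 47, b1 = 1, h2o = 0.7, t2 = NULL)
  steamLocalValues(t1Steam = t1, t2starSteam = t2star, b1Steam = b1,
                   h2oMeanSteam = h2o, t2Steam = t2)

test_that("STEAM correction factors match their closed forms", {
  acq <- steamAcquisition(1, tr = 10000, te = 20, tm = 10)
  geom32 <- mrsiGeometry(matrixSize = c(32L, 32L))   # 7.5 x 7.5 x 12 voxels
  fac <- steamCorrectionFactors(acq, steamLoc(t1 = 1000, t2 = 59, b1 = 0.9),
                                geom32)
  expect_equal(fac$t1corr, 1 / ((1 - exp(-9.98)) * exp(-0.01)),
               tolerance = 1e-12)
  expect_equal(fac$t1corr, 1.0101, tolerance = 1e-4)
  expect_equal(fac$t2corr, exp(20 / 59), tolerance = 1e-12)
  expect_equal(fac$t2corr, 1.4035, tolerance = 1e-4)
  expect_equal(fac$b1corr, 1 / sin(0.9 * pi / 2)^3, tolerance = 1e-12)
  expect_equal(fac$b1corr, 1.0379, tolerance = 1e-4)
  expect_equal(fac$voxelcorr, 675 / 1000, tolerance = 1e-12)
})

test_that("a perfect flip needs no transmit correction", {
  fac <- steamCorrectionFactors(steamAcquisition(1), steamLoc(b1 = 1),
                                mrsiGeometry())
  expect_equal(fac$b1corr, 1, tolerance = 1e-12)
  # cubed-numerator variant coincides at the nominal 90 degrees
  fac2 <- steamCorrectionFactors(steamAcquisition(1), steamLoc(b1 = 0.9),
                                 mrsiGeometry(), cubedNumerator = TRUE)
  fac3 <- steamCorrectionFactors(steamAcquisition(1), steamLoc(b1 = 0.9),
                                 mrsiGeometry())
  expect_equal(fac2$b1corr, fac3$b1corr, tolerance = 1e-12)
})

test_that("all factors approach one in the no-attenuation limit", {
  acq <- steamAcquisition(1, tr = 1e9, te = 1e-6, tm = 1e-6)
  geomEq <- mrsiGeometry(matrixSize = c(24L, 24L), sliceThicknessMm = 10)
  fac <- steamCorrectionFactors(acq, steamLoc(b1 = 1), geomEq)
  for (f in fac) expect_equal(f, 1, tolerance = 1e-6)
  out <- correctSteamSignal(acq, steamLoc(b1 = 1), geomEq, halfSignal = FALSE)
  expect_equal(as.numeric(out), 1, tolerance = 1e-6)
})

test_that("relaxation corrections undo attenuation (factors >= 1)", {
  acq <- steamAcquisition(1)
  for (t1 in c(600, 830, 1300, 4300)) {
    for (t2s in c(30, 47, 80)) {
      fac <- steamCorrectionFactors(acq, steamLoc(t1 = t1, t2star = t2s),
                                    mrsiGeometry())
      expect_gte(fac$t1corr, 1)
      expect_gte(fac$t2corr, 1)
    }
  }
  # strict as-printed mode returns the attenuation itself
  facP <- steamCorrectionFactors(acq, steamLoc(), mrsiGeometry(),
                                 asPrinted = TRUE)
  facR <- steamCorrectionFactors(acq, steamLoc(), mrsiGeometry())
  expect_equal(facP$t1corr, 1 / facR$t1corr, tolerance = 1e-12)
  expect_lt(facP$t1corr, 1)
})

test_that("the corrected STEAM amplitude is the product of its parts", {
  acq <- steamAcquisition(1, tr = 10000, te = 20, tm = 10)
  geom32 <- mrsiGeometry(matrixSize = c(32L, 32L))
  loc <- steamLoc(t1 = 1000, t2 = 59, b1 = 0.9)
  out <- correctSteamSignal(acq, loc, geom32)
  fac <- attr(out, "factors")
  oracle <- 2 * (1 / ((1 - exp(-9.98)) * exp(-0.01))) * exp(20 / 59) *
    (1 / sin(0.9 * pi / 2)^3) * 0.675
  expect_equal(as.numeric(out), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(out), 1.9862, tolerance = 2e-4)
  # linearity in the measured amplitude
  out2 <- correctSteamSignal(steamAcquisition(2, tr = 10000, te = 20, tm = 10),
                             loc, geom32)
  expect_equal(as.numeric(out2), 2 * as.numeric(out), tolerance = 1e-12)
})

test_that("excessive transmit scaling trips the flip-angle guard", {
  expect_error(
    steamCorrectionFactors(steamAcquisition(1), steamLoc(b1 = 2.1),
                           mrsiGeometry()),
    "flip")
})

test_that("the synthesized reference self-calibrates and is H2O-scale invariant", {
  h2o <- voxelMap(matrix(0.7, 4, 4), unit = "fraction",
                  voxelMm = c(60, 60, 12), originMm = c(-90, -90, 0))
  w <- synthesizeWaterReference(100, h2o, 0.7)
  expect_lt(max(abs(mapValues(w) - 100)), 1e-12)

  h2o2 <- voxelMap(matrix(0.56, 1, 1), unit = "fraction",
                   voxelMm = c(240, 240, 12))
  expect_equal(mapValues(synthesizeWaterReference(100, h2o2, 0.70))[1, 1, 1],
               80, tolerance = 1e-12)

  wScaled <- synthesizeWaterReference(100, voxelMap(mapValues(h2o) * 3,
                                                    mapAffine(h2o), "fraction"),
                                      0.7 * 3)
  expect_equal(mapValues(wScaled), mapValues(w), tolerance = 1e-12)
  expect_error(synthesizeWaterReference(100, h2o, 0), "> 0")
})

test_that("the synthesized reference equals the relaxation-corrected acquired water", {
  ph <- smallPhantom(seed = 9)
  pw <- proposedWaterReference(ph$steam, ph$maps$t1, ph$maps$t2star,
                               ph$maps$b1, ph$maps$h2o, ph$geom,
                               table = ph$table)
  # relaxation-correct the directly simulated water grid
  cfg <- ph$config
  aW <- waterAttenuationSE(mapValues(ph$maps$t1), mapValues(ph$maps$t2),
                           cfg$slaserTr, cfg$slaserTe)
  num <- mapValues(resliceToMRSI(
    voxelMap(mapValues(ph$maps$h2o) * aW, mapAffine(ph$maps$h2o), "a.u."),
    ph$geom))[, , 1]
  den <- mapValues(ph$h2oMrsi)[, , 1]
  corrected <- ph$truth$swClean / (num / den)
  expect_lt(max(abs(mapValues(pw$waterRef)[, , 1] / corrected - 1)), 1e-3)
})

test_that("K is unity on a consistent phantom and tracks a gain mismatch", {
  ph <- smallPhantom(seed = 4)
  pw <- proposedWaterReference(ph$steam, ph$maps$t1, ph$maps$t2star,
                               ph$maps$b1, ph$maps$h2o, ph$geom,
                               table = ph$table)
  cfg <- ph$config
  aW <- waterAttenuationSE(mapValues(ph$maps$t1), mapValues(ph$maps$t2),
                           cfg$slaserTr, cfg$slaserTe)
  num <- resliceToMRSI(voxelMap(mapValues(ph$maps$h2o) * aW,
                                mapAffine(ph$maps$h2o), "a.u."), ph$geom)
  att <- voxelMap(mapValues(num)[, , 1] / mapValues(ph$h2oMrsi)[, , 1],
                  mapAffine(ph$h2oMrsi), "relative")
  k1 <- kFactor(ph$sw, ph$fractionsPsf, ph$h2oMrsi, att, pw$svCorr,
                pw$local@h2oMeanSteam)
  expect_equal(k1, 1, tolerance = 1e-6)

  swScaled <- voxelMap(mapValues(ph$sw) * 1.1, mapAffine(ph$sw), "a.u.")
  k2 <- kFactor(swScaled, ph$fractionsPsf, ph$h2oMrsi, att, pw$svCorr,
                pw$local@h2oMeanSteam)
  expect_equal(k2, 1.1, tolerance = 1e-6)

  expect_error(
    kFactor(ph$sw, ph$fractionsPsf, ph$h2oMrsi, att, pw$svCorr,
            pw$local@h2oMeanSteam, threshold = 1.5),
    "STEAM voxel")
})
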