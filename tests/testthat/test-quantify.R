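test_that("metabolite relaxation factor follows its closed form", {
  expect_equal(metaboliteRelaxationFactor(1400, 200, 2000, 40),
               exp(-0.2) * (1 - exp(-2000 / 1400)), tolerance = 1e-12)
  expect_equal(metaboliteRelaxationFactor(1400, 200, 2000, 40), 0.6225,
               tolerance = 1e-4)
  expect_lt(abs(metaboliteRelaxationFactor(1400, 200, 1e9, 1e-9) - 1), 1e-9)
  rm1 <- metaboliteRelaxationFactor(1400, seq(100, 300, 50), 2000, 40)
  expect_true(all(diff(rm1) > 0))
})

test_that("CSF molal water fraction handles edge cases", {
  expect_equal(csfWaterFraction(0, 1, 0.7)$value, 0)
  expect_equal(csfWaterFraction(0.2, 1, 0.8)$value, 0.25, tolerance = 1e-12)
  over <- csfWaterFraction(0.9, 1, 0.8)
  expect_false(over$valid)
  expect_true(is.nan(csfWaterFraction(0.2, 1, 0)$value))
})

test_that("molal to molar conversion implements the CSF-excluding water scaling", {
  expect_equal(molalToMolar(10, 1, 0), 10)
  expect_equal(molalToMolar(10, 0.8, 0.2), 10 * 0.75, tolerance = 1e-12)
  expect_equal(molalToMolar(10, 0.5, 0.5), 0)
  expect_true(is.nan(molalToMolar(10, 0.8, 1)))
})

test_that("the proposed-method arithmetic chain is exact on a toy voxel", {
  one <- matrix(1, 1, 1)
  tab <- defaultRelaxationTable()
  tab@metabolites <- data.frame(name = "X", t1 = 1e-9, t2 = 1e12)  # RM = 1
  sm <- metaboliteAmplitudeSet(list(X = 2e-4 * one), tr = 2000, te = 40)
  fr <- tissueFractionMap(one, 0 * one, 0 * one)
  res <- quantifyProposed(sm, one, fr, one, tab)
  expect_equal(molalMaps(res)$X[1, 1], 11.02, tolerance = 1e-9)
  # zero amplitude maps to zero concentration
  sm0 <- metaboliteAmplitudeSet(list(X = 0 * one), tr = 2000, te = 40)
  expect_equal(molalMaps(quantifyProposed(sm0, one, fr, one, tab))$X[1, 1], 0)
})

test_that("every method recovers a noise-free phantom to better than 0.1%", {
  ph <- smallPhantom(seed = 21)
  res <- quantifyAllMethods(ph)
  for (m in c("ref", "ref_qmri", "proposed")) {
    expect_gt(sum(validMask(res[[m]])), 100)
    expect_lt(maxRecoveryError(res[[m]], ph), 1e-3)
  }
})

test_that("the molar/molal link holds voxel-wise on every output", {
  ph <- smallPhantom(seed = 22, noiseSigma = 0.02)
  res <- quantifyAllMethods(ph)
  for (m in c("ref", "ref_qmri", "proposed")) {
    conc <- res[[m]]
    pv <- provenance(conc)
    fac <- (pv$h2oMap - pv$fCsfMap) / (1 - pv$fCsfMap) * pv$rhoW
    ok <- validMask(conc)
    for (nm in names(molalMaps(conc))) {
      lhs <- molarMaps(conc)[[nm]][ok]
      rhs <- (molalMaps(conc)[[nm]] * fac)[ok]
      expect_lt(max(abs(lhs - rhs)), 1e-9)
    }
  }
})

test_that("longer true relaxation than the table causes underestimation by literature scaling", {
  ph <- smallPhantom(seed = 23, relaxationScale = c(t2 = 1.5))
  res <- quantifyAllMethods(ph)
  ok <- validMask(res$ref) & validMask(res$ref_qmri)
  # qMRI scaling still recovers the truth
  expect_lt(maxRecoveryError(res$ref_qmri, ph), 1e-3)
  # literature scaling is biased low in every valid voxel, for every metabolite
  for (nm in names(molalMaps(res$ref))) {
    d <- molalMaps(res$ref)[[nm]][ok] - molalMaps(res$ref_qmri)[[nm]][ok]
    expect_true(all(d < 0))
  }
})

test_that("concentrations are invariant to a global scanner gain", {
  ph1 <- smallPhantom(seed = 24, noiseSigma = 0.01, gain = 1)
  ph2 <- smallPhantom(seed = 24, noiseSigma = 0.01, gain = 3.7)
  r1 <- quantifyAllMethods(ph1)
  r2 <- quantifyAllMethods(ph2)
  for (m in c("ref", "ref_qmri", "proposed")) {
    ok <- validMask(r1[[m]]) & validMask(r2[[m]])
    for (nm in names(molalMaps(r1[[m]]))) {
      rel <- abs(molalMaps(r2[[m]])[[nm]][ok] /
                   molalMaps(r1[[m]])[[nm]][ok] - 1)
      expect_lt(max(rel), 1e-9)
    }
  }
})

test_that("the T2* fallback reproduces the measured-T2 correction in calibrated WM", {
  # uniform calibrated-WM relaxation everywhere, so the constant T2*
  # calibration is exact in every voxel the PSF can mix
  wmRow <- data.frame(compartment = c("gm", "wm", "csf"),
                      t1 = 830, t2 = 80, t2star = 80 * 47 / 59, h2o = 0.65)
  ph <- smallPhantom(seed = 25, tissue = wmRow)
  rqMeasured <- quantifyRefQmri(ph$sm, ph$sw, ph$fractionsPsf, ph$maps$t1,
                                ph$maps$h2o, ph$geom, t2Hr = ph$maps$t2,
                                table = ph$table)
  rqFallback <- quantifyRefQmri(ph$sm, ph$sw, ph$fractionsPsf, ph$maps$t1,
                                ph$maps$h2o, ph$geom,
                                t2starHr = ph$maps$t2star, table = ph$table)
  ok <- validMask(rqMeasured) & validMask(rqFallback)
  expect_gt(sum(ok), 100)
  for (nm in names(molalMaps(rqMeasured))) {
    rel <- abs(molalMaps(rqFallback)[[nm]][ok] /
                 molalMaps(rqMeasured)[[nm]][ok] - 1)
    expect_lt(max(rel), 1e-9)
  }
})

test_that("proposed and qMRI scaling agree on a calibrated noise-free phantom", {
  ph <- smallPhantom(seed = 26)
  res <- quantifyAllMethods(ph)
  ok <- validMask(res$proposed) & validMask(res$ref_qmri)
  for (nm in names(molalMaps(res$proposed))) {
    rel <- abs(molalMaps(res$proposed)[[nm]][ok] /
                 molalMaps(res$ref_qmri)[[nm]][ok] - 1)
    expect_lt(max(rel), 0.005)
  }
})

test_that("metabolites absent from the relaxation table are refused", {
  one <- matrix(1, 1, 1)
  sm <- metaboliteAmplitudeSet(list(mIns = one))
  fr <- tissueFractionMap(one, 0 * one, 0 * one)
  expect_error(quantifyProposed(sm, one, fr, one), "mIns")
})

test_that("CSF-dominated voxels are flagged invalid, not zeroed", {
  ph <- smallPhantom(seed = 27)
  res <- quantifyAllMethods(ph)
  csfHeavy <- fCSF(ph$fractionsPsf) >= 0.95
  if (any(csfHeavy)) {
    for (m in c("ref", "ref_qmri", "proposed"))
      expect_true(all(!validMask(res[[m]])[csfHeavy]))
  }
  # and valid voxels are never silently zero
  expect_true(all(molalMaps(res$ref)$tNAA[validMask(res$ref)] > 0))
})
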