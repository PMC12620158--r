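test_that("constant fields are fixed points of reslicing for every PSF", {
  hr <- makeHrMap(0.7, unit = "fraction")
  for (mode in c("fourier", "hamming", "box")) {
    out <- resliceToMRSI(hr, smallGeom(), psf = mode)
    expect_lt(max(abs(mapValues(out) - 0.7)), 1e-9)
    expect_identical(mapUnit(out), "fraction")
  }
})

test_that("impulse response matches the brute-force k-space truncation oracle", {
  n <- 32L; sp <- 240 / n
  geom <- smallGeom()
  f <- matrix(0, n, n)
  f[11, 19] <- 1
  hr <- makeHrMap(f, n = c(n, n, 4L), sp = c(sp, sp, 5))
  u <- mrsiFractions(geom, n, sp)
  for (win in c("tophat", "hamming")) {
    mode <- if (win == "tophat") "fourier" else "hamming"
    got <- mapValues(resliceToMRSI(hr, geom, psf = mode))[, , 1]
    want <- truncationOracle(f, 8L, u$x, u$y, window = win)
    expect_lt(max(abs(got - want)), 1e-9)
  }
  # mean preservation: total over the MRSI grid scales with grid areas
  got <- mapValues(resliceToMRSI(hr, geom, psf = "fourier"))[, , 1]
  expect_lt(abs(sum(got) - prod(dim(got)) / n^2), 1e-9)
})

test_that("a checkerboard at the MRSI Nyquist frequency is attenuated as the oracle predicts", {
  n <- 32L; sp <- 240 / n
  geom <- smallGeom()               # 8 x 8: Nyquist = 4 cycles / FOV
  j <- 0:(n - 1)
  f <- outer(cos(2 * pi * 4 * j / n), cos(2 * pi * 4 * j / n))
  hr <- makeHrMap(f, n = c(n, n, 4L), sp = c(sp, sp, 5))
  u <- mrsiFractions(geom, n, sp)
  got <- mapValues(resliceToMRSI(hr, geom, psf = "fourier"))[, , 1]
  want <- truncationOracle(f, 8L, u$x, u$y)
  expect_lt(max(abs(got - want)), 1e-9)
  # the truncated band keeps only one of the two Nyquist exponentials
  expect_lt(max(abs(got)), max(abs(f)))
  expect_gt(max(abs(got)), 0.1)
})

test_that("reslicing is linear", {
  set.seed(42)
  geom <- smallGeom()
  for (rep in 1:3) {
    x <- matrix(rnorm(48 * 48), 48, 48)
    y <- matrix(rnorm(48 * 48), 48, 48)
    a <- rnorm(1); b <- rnorm(1)
    rx <- mapValues(resliceToMRSI(makeHrMap(x), geom))[, , 1]
    ry <- mapValues(resliceToMRSI(makeHrMap(y), geom))[, , 1]
    rxy <- mapValues(resliceToMRSI(makeHrMap(a * x + b * y), geom))[, , 1]
    expect_lt(max(abs(rxy - (a * rx + b * ry))), 1e-9)
  }
})

test_that("the discretized PSF kernel integrates to one", {
  for (win in c("tophat", "hamming")) {
    k <- psfKernel(smallGeom(), hrMatrix = c(48L, 48L), window = win)
    expect_lt(abs(sum(k) - 1), 1e-9)
  }
  k <- psfKernel(mrsiGeometry(), hrMatrix = c(96L, 96L))
  expect_lt(abs(sum(k) - 1), 1e-9)
})

test_that("NaN voxels propagate to the MRSI voxels they influence", {
  f <- matrix(0.7, 48, 48)
  f[20:23, 20:23] <- NaN
  out <- mapValues(resliceToMRSI(makeHrMap(f), smallGeom(), psf = "box"))[, , 1]
  expect_true(any(is.nan(out)))
  expect_lt(max(abs(out[is.finite(out)] - 0.7)), 1e-9)
  # Fourier mode: contaminated voxels NaN, remote voxels renormalized cleanly
  outF <- mapValues(resliceToMRSI(makeHrMap(f), smallGeom(),
                                  psf = "fourier"))[, , 1]
  expect_true(any(is.nan(outF)))
  expect_lt(max(abs(outF[is.finite(outF)] - 0.7)), 1e-3)
})

test_that("disjoint geometries and mismatched FOVs are rejected", {
  hr <- makeHrMap(1)
  far <- mrsiGeometry(centerMm = c(1000, 0, 0))
  expect_error(resliceToMRSI(hr, far), "overlap")
  tooThin <- makeHrMap(1, n = c(48L, 48L, 1L))
  expect_error(resliceToMRSI(tooThin, smallGeom()), "slab")
  wrongFov <- voxelMap(array(1, c(20, 20, 8)), unit = "a.u.",
                       voxelMm = c(5, 5, 5), originMm = c(-47.5, -47.5, -17.5))
  expect_error(resliceToMRSI(wrongFov, smallGeom(), psf = "fourier"), "FOV")
})

test_that("reslicing reproduces the phantom's noise-free water amplitudes", {
  ph <- smallPhantom(seed = 11)
  cfg <- ph$config
  aW <- waterAttenuationSE(mapValues(ph$maps$t1), mapValues(ph$maps$t2),
                           cfg$slaserTr, cfg$slaserTe)
  hr <- voxelMap(mapValues(ph$maps$h2o) * aW,
                 affine = mapAffine(ph$maps$h2o), unit = "a.u.")
  sw <- ph$truth$waterScale * mapValues(resliceToMRSI(hr, ph$geom))[, , 1]
  expect_lt(max(abs(sw / ph$truth$swClean - 1)), 1e-9)
})

test_that("steamRegionMean averages covered voxel centers", {
  hr <- voxelMap(array(c(40, 60), c(2, 1, 1)), unit = "ms",
                 voxelMm = c(5, 5, 5), originMm = c(-2.5, 0, 0))
  m <- steamRegionMean(hr, steamVoxelGeometry(c(0, 0, 0), c(10, 5, 5)))
  expect_equal(as.numeric(m), 50)
  expect_equal(attr(m, "n"), 2L)

  const <- makeHrMap(3.3)
  expect_equal(as.numeric(steamRegionMean(const, steamVoxelGeometry())), 3.3)

  withNan <- array(c(40, NaN, 60, 80), c(4, 1, 1))
  hr2 <- voxelMap(withNan, unit = "ms", voxelMm = c(5, 5, 5),
                  originMm = c(-7.5, 0, 0))
  m2 <- steamRegionMean(hr2, steamVoxelGeometry(c(0, 0, 0), c(20, 5, 5)))
  expect_equal(as.numeric(m2), 60)
  expect_equal(attr(m2, "nValid"), 3L)

  expect_error(steamRegionMean(const, steamVoxelGeometry(c(500, 0, 0))),
               "intersect")
})
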