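test_that("noise-free exponentials are recovered exactly", {
  tes <- c(25, 50, 75)
  f <- fitT2Mono(exp(-tes / 50), tes)
  expect_equal(f$t2, 50, tolerance = 1e-9)
  expect_equal(f$s0, 1, tolerance = 1e-9)
  expect_identical(f$flag, "ok")

  for (t2 in c(10, 59, 80, 300, 1200, 4000)) {
    f <- fitT2Mono(3.2 * exp(-tes / t2), tes)
    expect_lt(abs(f$t2 / t2 - 1), 1e-9)
    expect_lt(abs(f$s0 / 3.2 - 1), 1e-9)
    fr <- fitT2Mono(3.2 * exp(-tes / t2), tes, refine = TRUE)
    expect_lt(abs(fr$t2 / t2 - 1), 1e-6)
  }
})

test_that("the two-point log-ratio closed form agrees with the fit", {
  s <- c(0.82, 0.31)
  tes <- c(25, 75)
  oracle <- (75 - 25) / log(s[1] / s[2])   # analytic two-point solution
  f <- fitT2Mono(s, tes)
  expect_equal(f$t2, oracle, tolerance = 1e-9)
})

test_that("degenerate decay inputs yield NaN with a flag", {
  expect_identical(fitT2Mono(c(1, 1, 1), c(25, 50, 75))$flag, "degenerate")
  expect_true(is.nan(fitT2Mono(c(1, 1, 1), c(25, 50, 75))$t2))
  expect_identical(fitT2Mono(c(1, 2, 3), c(25, 50, 75))$flag, "degenerate")
  expect_identical(fitT2Mono(c(-1, -2, 0.5), c(25, 50, 75))$flag, "degenerate")
  expect_error(fitT2Mono(c(1, 2), c(25, 25)), "distinct")
})

test_that("median T2 bias stays below 1% at SNR 50", {
  set.seed(2027)
  tes <- c(25, 50, 75)
  clean <- exp(-tes / 59)
  est <- replicate(1000, {
    fitT2Mono(clean * (1 + rnorm(3) / 50), tes)$t2
  })
  expect_lt(abs(median(est, na.rm = TRUE) / 59 - 1), 0.01)
})

test_that("the vectorized T2 map equals the per-voxel fit", {
  set.seed(7)
  tes <- c(25, 50, 75)
  t2true <- array(runif(3 * 3 * 2, 40, 200), c(3, 3, 2))
  s0true <- array(runif(3 * 3 * 2, 0.5, 4), c(3, 3, 2))
  arr <- array(NA_real_, c(3, 3, 2, 3))
  for (k in 1:3) arr[, , , k] <- s0true * exp(-tes[k] / t2true)
  fm <- fitT2Map(arr, tes)
  expect_lt(max(abs(mapValues(fm$t2) / t2true - 1)), 1e-9)
  expect_lt(max(abs(mapValues(fm$s0) / s0true - 1)), 1e-9)
  # degenerate voxel handled voxel-wise
  arr[1, 1, 1, ] <- 1
  fm2 <- fitT2Map(arr, tes)
  expect_true(is.nan(mapValues(fm2$t2)[1, 1, 1]))
  expect_false(anyNA(mapValues(fm2$t2)[-1]))
})

test_that("the constant T2* calibration is linear and order-preserving", {
  expect_equal(t2FromT2star(47), 59, tolerance = 1e-12)
  expect_equal(t2FromT2star(40), 40 * 59 / 47, tolerance = 1e-12)
  x <- c(20, 47, 60, 90)
  y <- t2FromT2star(x)
  expect_true(all(diff(y) > 0))
  expect_equal(t2FromT2star(2 * x), 2 * y, tolerance = 1e-12)
  expect_true(is.nan(t2FromT2star(-3)))
  expect_true(is.nan(t2FromT2star(0)))
})

test_that("spin-echo water attenuation follows its closed form and monotonicity", {
  expect_equal(waterAttenuationSE(1000, 59, 2000, 40),
               exp(-40 / 59) * (1 - exp(-2)), tolerance = 1e-12)
  # limits: vanishing TE and long TR
  expect_lt(abs(waterAttenuationSE(1000, 59, 1e9, 1e-9) - 1), 1e-9)
  # increasing in t2 and tr, decreasing in te
  expect_gt(waterAttenuationSE(1000, 80, 2000, 40),
            waterAttenuationSE(1000, 59, 2000, 40))
  expect_gt(waterAttenuationSE(1000, 59, 4000, 40),
            waterAttenuationSE(1000, 59, 2000, 40))
  expect_lt(waterAttenuationSE(1000, 59, 2000, 60),
            waterAttenuationSE(1000, 59, 2000, 40))
  expect_true(is.nan(waterAttenuationSE(-1, 59, 2000, 40)))
})
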