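# Monoexponential T2 estimation and relaxation attenuation factors.

#' Monoexponential T2 fit
#'
#' Fits `S(TE) = S0 * exp(-TE / T2)` to amplitudes measured at two or more
#' echo times. The default estimator is weighted log-linear least squares
#' (weights S^2, the standard linearization for amplitude-proportional
#' noise); `refine = TRUE` follows with a nonlinear least-squares
#' refinement. The decay model itself has no free amplitude in its usual
#' printed form; a two-parameter fit with S0 is used because measured
#' signals are not normalized.
#'
#' Non-positive amplitudes are dropped. Degenerate inputs (fewer than two
#' valid points, or a non-decaying signal) yield `T2 = NaN` with
#' `flag = "degenerate"`.
#'
#' @param signals Numeric vector of amplitudes.
#' @param tes Echo times in ms, same length.
#' @param refine Logical; run a nonlinear refinement after the log-linear
#'   fit.
#' @return List with `t2` (ms), `s0`, and `flag` ("ok" or "degenerate").
#' @examples
#' fitT2Mono(exp(-c(25, 50, 75) / 50), c(25, 50, 75))   # t2 = 50, s0 = 1
#' @export
fitT2Mono <- function(signals, tes, refine = FALSE) {
  stopifnot(length(signals) == length(tes))
  if (length(unique(tes)) < 2L) stop("need at least 2 distinct echo times")
  ok <- is.finite(signals) & is.finite(tes) & signals > 0
  bad <- list(t2 = NaN, s0 = NaN, flag = "degenerate")
  if (sum(ok) < 2L || length(unique(tes[ok])) < 2L) return(bad)
  s <- signals[ok]; x <- tes[ok]
  y <- log(s)
  w <- s^2
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xm)^2)
  if (sxx <= 0) return(bad)
  slope <- sum(w * (x - xm) * (y - ym)) / sxx
  if (slope >= 0) return(bad)
  t2 <- -1 / slope
  s0 <- exp(ym - slope * xm)
  if (refine) {
    fit <- tryCatch(
      stats::nls(s ~ a * exp(-x / b), start = list(a = s0, b = t2),
                 algorithm = "port", lower = c(1e-12, 1e-6)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      s0 <- unname(co["a"]); t2 <- unname(co["b"])
    }
  }
  list(t2 = t2, s0 = s0, flag = "ok")
}

#' Voxel-wise T2 map from multi-echo spin-echo images
#'
#' Applies [fitT2Mono()] to every voxel of a stack of echo images (the
#' log-linear closed form, vectorized). Voxels with degenerate signals get
#' NaN.
#'
#' @param echoes List of [VoxelMap-class] objects (one per TE) on a common
#'   grid, or a 4D array with the echo dimension last.
#' @param tes Echo times in ms (e.g., `c(25, 50, 75)`).
#' @return A list with `t2` and `s0` [VoxelMap-class] objects (unit "ms" and
#'   "a.u.").
#' @export
fitT2Map <- function(echoes, tes) {
  if (is.list(echoes)) {
    aff <- mapAffine(echoes[[1]])
    arr <- vapply(echoes, mapValues, mapValues(echoes[[1]]))
  } else {
    aff <- diag(4)
    arr <- echoes
  }
  d <- dim(arr)
  stopifnot(length(d) == 4L, d[4] == length(tes))
  n <- prod(d[1:3])
  s <- matrix(arr, n, d[4])
  ok <- is.finite(s) & s > 0
  s[!ok] <- NA
  y <- log(s)
  w <- s^2
  w[!ok] <- 0
  x <- matrix(tes, n, d[4], byrow = TRUE)
  sw <- rowSums(w)
  xm <- rowSums(w * x) / sw
  ym <- rowSums(w * y, na.rm = TRUE) / sw
  dx <- x - xm
  sxx <- rowSums(w * dx^2)
  slope <- rowSums(w * dx * (y - ym), na.rm = TRUE) / sxx
  t2 <- -1 / slope
  s0 <- exp(ym - slope * xm)
  degen <- rowSums(ok) < 2 | !is.finite(slope) | slope >= 0
  t2[degen] <- NaN
  s0[degen] <- NaN
  list(t2 = new("VoxelMap", values = array(t2, d[1:3]), affine = aff,
                unit = "ms"),
       s0 = new("VoxelMap", values = array(s0, d[1:3]), affine = aff,
                unit = "a.u."))
}

#' Estimate water T2 from T2* by the constant WM calibration
#'
#' Multiplies T2* by the ratio of the literature WM T2 to the literature WM
#' T2* (59/47 = 1.255 with the default table). Non-positive inputs yield
#' NaN. The mapping is linear and order-preserving.
#'
#' @param t2star T2* in ms (vector or array).
#' @param table A [RelaxationTable-class] supplying the two constants.
#' @return T2 estimate in ms, same shape as `t2star`.
#' @examples
#' t2FromT2star(47)    # 59
#' @export
t2FromT2star <- function(t2star, table = defaultRelaxationTable()) {
  k <- table@constants$wmT2LitMs / table@constants$wmT2starLitMs
  out <- t2star * k
  out[!is.finite(t2star) | t2star <= 0] <- NaN
  out
}

#' Spin-echo water attenuation factor
#'
#' `exp(-TE/T2) * (1 - exp(-TR/T1))`: the fraction of the fully relaxed
#' water signal observed by a spin-echo sequence. Used by both reference
#' water-scaling methods; its reciprocal undoes the relaxation loss.
#'
#' @param t1,t2 Water relaxation times in ms (> 0; vectorized).
#' @param tr,te Sequence repetition/echo time in ms (> 0).
#' @return Attenuation in (0, 1].
#' @examples
#' waterAttenuationSE(1000, 59, 2000, 40)   # 0.4390
#' @export
waterAttenuationSE <- function(t1, t2, tr, te) {
  stopifnot(all(tr > 0), all(te > 0))
  out <- exp(-te / t2) * (1 - exp(-tr / t1))
  out[(!is.finite(t1) | t1 <= 0) | (!is.finite(t2) | t2 <= 0)] <- NaN
  out
}
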