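# Reslicing of high-resolution maps into MRSI space.
#
# The MRSI grid samples k-space on a small phase-encode matrix, so each MRSI
# voxel sees the underlying tissue through a broad point spread function
# (PSF). Reslicing therefore (1) collapses the HR map across the slice
# profile (box overlap weights) and (2) applies the in-plane PSF as an ideal
# k-space truncation of the HR field to the MRSI matrix, optionally with a
# Hamming window mimicking weighted phase encoding, then samples the
# truncated field at the MRSI voxel centers. A plain box average (no PSF) is
# also available and is the default for tissue fractions.

.windowWeights <- function(q, m, window) {
  switch(window,
    tophat = rep(1, length(q)),
    hamming = 0.54 + 0.46 * cos(pi * q / (m / 2)),
    stop("unknown k-space window: ", window))
}

# collapse HR volume across the MRSI slice profile -> 2D field (+ weights used)
.sliceCollapse <- function(vals, zCenters, dz, geom) {
  z0 <- geom@pose[3, 4]
  th <- geom@sliceThicknessMm
  lo <- z0 - th / 2
  hi <- z0 + th / 2
  ov <- pmin(zCenters + dz / 2, hi) - pmax(zCenters - dz / 2, lo)
  w <- pmax(ov, 0) / dz
  if (sum(w) * dz < th - dz / 2 + 1e-9)
    stop("HR map does not cover the MRSI slab in the slice direction")
  keep <- which(w > 0)
  f <- 0
  for (k in keep) f <- f + w[k] * vals[, , k]
  f / sum(w[keep])
}

# in-plane Fourier-truncation reslice of a 2D field sampled on the HR grid;
# `origin` is the world position of the center of HR voxel (0, 0), i.e. the
# DFT anchors sample j at periodic-domain fraction j/N
.fourierReslice <- function(f2d, hrSp, origin, geom, window) {
  Nx <- nrow(f2d); Ny <- ncol(f2d)
  Lx <- Nx * hrSp[1]; Ly <- Ny * hrSp[2]
  if (abs(Lx - geom@fovMm[1]) > hrSp[1] / 2 + 1e-6 ||
      abs(Ly - geom@fovMm[2]) > hrSp[2] / 2 + 1e-6)
    stop("HR in-plane extent must match the MRSI FOV for PSF reslicing")
  cen <- voxelCenters(geom)
  ux <- (cen$x - origin[1]) / Lx
  uy <- (cen$y - origin[2]) / Ly
  tolx <- 0.5 / Nx + 1e-9; toly <- 0.5 / Ny + 1e-9
  if (any(ux < -tolx | ux > 1 + tolx) || any(uy < -toly | uy > 1 + toly))
    stop("MRSI grid does not overlap the HR map in-plane")
  mx <- geom@matrixSize[1]; my <- geom@matrixSize[2]
  qx <- seq.int(-floor(mx / 2), ceiling(mx / 2) - 1L)
  qy <- seq.int(-floor(my / 2), ceiling(my / 2) - 1L)
  Fk <- stats::fft(f2d)
  Fsub <- Fk[(qx %% Nx) + 1L, (qy %% Ny) + 1L, drop = FALSE]
  Fsub <- Fsub * outer(.windowWeights(qx, mx, window),
                       .windowWeights(qy, my, window))
  Ex <- exp(2i * pi * outer(ux, qx))
  Ey <- exp(2i * pi * outer(uy, qy))
  Re(Ex %*% Fsub %*% t(Ey)) / (Nx * Ny)
}

# in-plane box average: HR voxel centers binned into MRSI voxels
.boxReslice <- function(f2d, hrSp, fieldStart, geom) {
  Nx <- nrow(f2d); Ny <- ncol(f2d)
  xs <- fieldStart[1] + hrSp[1] * (seq_len(Nx) - 0.5)
  ys <- fieldStart[2] + hrSp[2] * (seq_len(Ny) - 0.5)
  o <- geom@pose[1:3, 4]
  dxm <- geom@fovMm / geom@matrixSize
  fovStart <- o[1:2] - dxm / 2
  ix <- floor((xs - fovStart[1]) / dxm[1] + 1e-9)
  iy <- floor((ys - fovStart[2]) / dxm[2] + 1e-9)
  mx <- geom@matrixSize[1]; my <- geom@matrixSize[2]
  okx <- ix >= 0 & ix < mx
  oky <- iy >= 0 & iy < my
  if (!any(okx) || !any(oky))
    stop("MRSI grid does not overlap the HR map in-plane")
  gx <- ix[okx] + 1L
  gy <- iy[oky] + 1L
  sub <- f2d[okx, oky, drop = FALSE]
  lin <- rep(gx, times = length(gy)) + (rep(gy, each = length(gx)) - 1L) * mx
  sums <- rep(0, mx * my)
  cnts <- rep(0, mx * my)
  agg <- rowsum(cbind(as.vector(sub), 1), lin)
  at <- as.integer(rownames(agg))
  sums[at] <- agg[, 1]
  cnts[at] <- agg[, 2]
  out <- matrix(sums / cnts, mx, my)
  out[matrix(cnts == 0, mx, my)] <- NaN
  out
}

.resliceField <- function(vals, hrSp, hrOrigin, geom, psf) {
  zCenters <- hrOrigin[3] + hrSp[3] * (seq_len(dim(vals)[3]) - 1)
  f2d <- .sliceCollapse(vals, zCenters, hrSp[3], geom)
  fieldStart <- hrOrigin[1:2] - hrSp[1:2] / 2
  switch(psf,
    fourier = .fourierReslice(f2d, hrSp, hrOrigin[1:2], geom, "tophat"),
    hamming = .fourierReslice(f2d, hrSp, hrOrigin[1:2], geom, "hamming"),
    box = .boxReslice(f2d, hrSp, fieldStart, geom))
}

#' Reslice a high-resolution map into MRSI space
#'
#' Collapses the HR map over the MRSI slice profile and applies the
#' spectroscopic point spread function in-plane: the HR field is truncated in
#' k-space to the MRSI phase-encode matrix (top-hat window; Hamming window
#' for weighted phase encoding) and sampled at the MRSI voxel centers. The
#' operator is linear and leaves constant fields unchanged.
#'
#' NaN handling: invalid HR voxels are excluded and the result renormalized
#' by the resliced validity weight; an MRSI voxel whose invalid PSF weight
#' exceeds `naThreshold` becomes NaN.
#'
#' @param hrMap A [VoxelMap-class] covering the MRSI slab (axis-aligned, same
#'   world frame as `geom`).
#' @param geom An [MRSIGeometry-class].
#' @param psf "fourier" (ideal k-space truncation), "hamming" (weighted phase
#'   encoding), or "box" (plain averaging, no PSF). Default follows
#'   `geom@weighting`: "uniform" -> "fourier", "weighted" -> "hamming".
#' @param naThreshold Invalid-weight fraction above which an output voxel is
#'   set to NaN.
#' @return A [VoxelMap-class] on the MRSI grid (matrix-size x 1), same unit.
#' @examples
#' hr <- voxelMap(array(0.7, c(48, 48, 6)), unit = "fraction",
#'                voxelMm = c(5, 5, 10), originMm = c(-117.5, -117.5, -25))
#' g <- mrsiGeometry()
#' range(mapValues(resliceToMRSI(hr, g)))   # constant field is preserved
#' @export
resliceToMRSI <- function(hrMap, geom, psf = NULL, naThreshold = 1e-3) {
  stopifnot(is(hrMap, "VoxelMap"), is(geom, "MRSIGeometry"))
  if (is.null(psf))
    psf <- if (geom@weighting == "weighted") "hamming" else "fourier"
  psf <- match.arg(psf, c("fourier", "hamming", "box"))
  sp <- affineSpacing(mapAffine(hrMap))
  o <- mapAffine(hrMap)[1:3, 4]
  vals <- mapValues(hrMap)
  if (anyNA(vals)) {
    valid <- is.finite(vals)
    filled <- vals
    filled[!valid] <- 0
    num <- .resliceField(filled, sp, o, geom, psf)
    wgt <- .resliceField(valid + 0, sp, o, geom, psf)
    out <- num / wgt
    out[!is.finite(out) | (1 - wgt) > naThreshold] <- NaN
  } else {
    out <- .resliceField(vals, sp, o, geom, psf)
  }
  dxm <- geom@fovMm / geom@matrixSize
  voxelMap(out, unit = mapUnit(hrMap),
           voxelMm = c(dxm, geom@sliceThicknessMm),
           originMm = geom@pose[1:3, 4])
}

#' Discretized MRSI point spread function
#'
#' Response of the reslicing operator to a unit point source, sampled on the
#' MRSI grid and normalized to unit sum. Useful for inspecting the PSF
#' implied by the k-space window.
#'
#' @param geom An [MRSIGeometry-class].
#' @param hrMatrix In-plane HR matrix size (length 2) on which the impulse
#'   is discretized.
#' @param window "tophat" or "hamming".
#' @param impulseIndex 1-based HR in-plane index of the point source; default
#'   is the grid center.
#' @return Matrix (MRSI grid) summing to 1.
#' @export
psfKernel <- function(geom, hrMatrix = c(96L, 96L),
                      window = c("tophat", "hamming"),
                      impulseIndex = NULL) {
  window <- match.arg(window)
  hrMatrix <- as.integer(hrMatrix)
  if (is.null(impulseIndex)) impulseIndex <- hrMatrix %/% 2L + 1L
  f <- matrix(0, hrMatrix[1], hrMatrix[2])
  f[impulseIndex[1], impulseIndex[2]] <- 1
  sp <- geom@fovMm / hrMatrix
  o <- geom@pose[1:3, 4]
  fovStart <- o[1:2] - (geom@fovMm / geom@matrixSize) / 2
  hrOrigin <- fovStart + sp / 2
  k <- .fourierReslice(f, sp, hrOrigin, geom,
                       if (window == "tophat") "tophat" else "hamming")
  # mean preservation of the operator implies this scaling has unit sum
  k * prod(hrMatrix) / prod(geom@matrixSize)
}

#' Tissue volume fractions on the MRSI grid
#'
#' Averages GM/WM/CSF probability maps (or a hard label map) into MRSI
#' voxels and renormalizes the three fractions to sum to one. Box averaging
#' is the default, matching common partial-volume practice; PSF-weighted
#' fractions (the same operator as [resliceToMRSI()]) are available via
#' `psf`.
#'
#' @param prob Either a named list of three [VoxelMap-class] probability maps
#'   (`gm`, `wm`, `csf`) summing to 1 per HR voxel, or a single integer label
#'   [VoxelMap-class] with codes 1 = GM, 2 = WM, 3 = CSF.
#' @param geom An [MRSIGeometry-class].
#' @param psf FALSE (default) for box averaging; TRUE, "fourier" or
#'   "hamming" for PSF-weighted fractions.
#' @return A [TissueFractionMap-class].
#' @export
tissueFractionsToMRSI <- function(prob, geom, psf = FALSE) {
  mode <- if (isFALSE(psf)) "box"
          else if (isTRUE(psf)) {
            if (geom@weighting == "weighted") "hamming" else "fourier"
          } else match.arg(psf, c("fourier", "hamming", "box"))
  if (is(prob, "VoxelMap")) {
    lab <- mapValues(prob)
    if (any(!is.na(lab) & !(lab %in% 0:3)))
      stop("label map codes must be 0 (background), 1 (GM), 2 (WM), 3 (CSF)")
    prob <- list(
      gm = voxelMap(array((lab == 1) + 0, dim(lab)), mapAffine(prob), "fraction"),
      wm = voxelMap(array((lab == 2) + 0, dim(lab)), mapAffine(prob), "fraction"),
      csf = voxelMap(array((lab == 3) + 0, dim(lab)), mapAffine(prob), "fraction"))
  }
  stopifnot(all(c("gm", "wm", "csf") %in% names(prob)))
  s <- 0
  for (nm in c("gm", "wm", "csf")) {
    v <- mapValues(prob[[nm]])
    if (any(is.finite(v) & (v < -1e-9 | v > 1 + 1e-9)))
      stop("tissue probabilities must lie in [0, 1]")
    s <- s + v
  }
  if (any(is.finite(s) & abs(s - 1) > 1e-6))
    stop("tissue probabilities must sum to 1 in every HR voxel")
  r <- lapply(prob[c("gm", "wm", "csf")], function(p)
    mapValues(resliceToMRSI(p, geom, psf = mode))[, , 1])
  tot <- r$gm + r$wm + r$csf
  tissueFractionMap(r$gm / tot, r$wm / tot, r$csf / tot)
}

#' Mean of a high-resolution map over the STEAM voxel
#'
#' NaN-aware mean over the HR voxels whose centers fall inside the box
#' (closed lower / open upper bounds). The count of covered and valid voxels
#' is attached as attributes `n` and `nValid`.
#'
#' @param hrMap A [VoxelMap-class].
#' @param box A [SteamVoxelGeometry-class].
#' @return Numeric scalar (NaN if no valid voxel), with attributes `n`,
#'   `nValid`.
#' @examples
#' hr <- voxelMap(array(c(40, 60), c(2, 1, 1)), unit = "ms",
#'                voxelMm = c(5, 5, 5), originMm = c(-2.5, 0, 0))
#' steamRegionMean(hr, steamVoxelGeometry(c(0, 0, 0), c(10, 5, 5)))  # 50
#' @export
steamRegionMean <- function(hrMap, box) {
  stopifnot(is(hrMap, "VoxelMap"), is(box, "SteamVoxelGeometry"))
  cen <- voxelCenters(hrMap)
  lo <- box@centerMm - box@dimsMm / 2
  hi <- box@centerMm + box@dimsMm / 2
  ix <- which(cen$x >= lo[1] - 1e-9 & cen$x < hi[1] - 1e-9)
  iy <- which(cen$y >= lo[2] - 1e-9 & cen$y < hi[2] - 1e-9)
  iz <- which(cen$z >= lo[3] - 1e-9 & cen$z < hi[3] - 1e-9)
  if (!length(ix) || !length(iy) || !length(iz))
    stop("STEAM box does not intersect the map")
  v <- mapValues(hrMap)[ix, iy, iz]
  out <- mean(v[is.finite(v)])
  attr(out, "n") <- length(v)
  attr(out, "nValid") <- sum(is.finite(v))
  out
}
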