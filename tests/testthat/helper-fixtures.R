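# Shared in-code fixtures and independent oracles.

# HR map whose in-plane extent matches a 240 mm FOV
makeHrMap <- function(values, unit = "a.u.", n = c(48L, 48L, 8L),
                      sp = c(5, 5, 5)) {
  if (is.matrix(values)) values <- array(values, c(dim(values), n[3]))
  if (length(values) == 1L) values <- array(values, n)
  ext <- n * sp
  voxelMap(values, unit = unit, voxelMm = sp,
           originMm = -ext / 2 + sp / 2)
}

smallGeom <- function(matrixSize = c(8L, 8L), ...)
  mrsiGeometry(fovMm = c(240, 240), matrixSize = matrixSize,
               sliceThicknessMm = 12, ...)

# Brute-force k-space truncation oracle: explicit DFT of a 2D HR field,
# truncation to the m x m MRSI matrix, evaluation at fractional positions
# ux/uy (sample j anchored at fraction j/N). Independent of the package's
# fft-based implementation.
truncationOracle <- function(f2d, m, ux, uy, window = "tophat") {
  N <- nrow(f2d)
  stopifnot(ncol(f2d) == N)
  qs <- seq.int(-floor(m / 2), ceiling(m / 2) - 1L)
  w <- switch(window,
              tophat = rep(1, length(qs)),
              hamming = 0.54 + 0.46 * cos(pi * qs / (m / 2)))
  j <- 0:(N - 1)
  out <- matrix(0 + 0i, length(ux), length(uy))
  for (a in seq_along(qs)) {
    for (b in seq_along(qs)) {
      Fq <- sum(f2d * outer(exp(-2i * pi * qs[a] * j / N),
                            exp(-2i * pi * qs[b] * j / N)))
      out <- out + w[a] * w[b] * Fq *
        outer(exp(2i * pi * qs[a] * ux), exp(2i * pi * qs[b] * uy))
    }
  }
  Re(out) / N^2
}

# fractional MRSI-center positions for a geometry over a matched HR field
mrsiFractions <- function(geom, n = 48L, sp = 5) {
  origin <- -n * sp / 2 + sp / 2
  cen <- voxelCenters(geom)
  list(x = (cen$x - origin) / (n * sp), y = (cen$y - origin) / (n * sp))
}

# quantify one phantom with all three methods (PSF-weighted fractions)
quantifyAllMethods <- function(ph) {
  tab <- ph$table
  rl <- quantifyRefLiterature(ph$sm, ph$sw, ph$fractionsPsf, tab)
  rq <- quantifyRefQmri(ph$sm, ph$sw, ph$fractionsPsf, ph$maps$t1,
                        ph$maps$h2o, ph$geom, t2Hr = ph$maps$t2, table = tab)
  pw <- proposedWaterReference(ph$steam, ph$maps$t1, ph$maps$t2star,
                               ph$maps$b1, ph$maps$h2o, ph$geom, table = tab)
  pr <- quantifyProposed(ph$sm, pw$waterRef, ph$fractionsPsf, pw$h2oMrsi, tab)
  list(ref = rl, ref_qmri = rq, proposed = pr, waterRef = pw)
}

# worst-case relative recovery error of a result against phantom truth
maxRecoveryError <- function(conc, ph) {
  ok <- validMask(conc)
  worst <- 0
  for (nm in names(molalMaps(conc))) {
    truth <- ph$truth$concentrations[[nm]]
    rel <- abs(molalMaps(conc)[[nm]][ok] / truth - 1)
    worst <- max(worst, max(rel))
  }
  worst
}

# small, fast phantom for unit tests (full 96x96x24 used in acceptance)
smallPhantom <- function(...) {
  generatePhantom(phantomConfig(hrMatrix = c(48L, 48L, 8L),
                                hrVoxelMm = c(5, 5, 5), ...))
}
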