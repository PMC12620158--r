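# ROI aggregation and Bland-Altman method-agreement statistics.

#' Default four-sector ROIs on the MRSI grid
#'
#' Anterior/posterior/left/right sectors of the spectroscopic VOI, split by
#' the dominant axis of each voxel center, restricted to an annulus and to
#' voxels with limited CSF content.
#'
#' @param geom An [MRSIGeometry-class].
#' @param fractions Optional [TissueFractionMap-class]; voxels with CSF
#'   fraction above `csfMax` are excluded.
#' @param radiusMm Inner/outer radius (mm) of the annulus kept.
#' @param csfMax Maximum CSF fraction.
#' @return Named list of logical matrices (anterior, posterior, left,
#'   right).
#' @export
defaultRois <- function(geom, fractions = NULL, radiusMm = c(18, 100),
                        csfMax = 0.3) {
  cen <- voxelCenters(geom)
  cx <- geom@pose[1, 4] + (geom@fovMm[1] / geom@matrixSize[1]) *
    (geom@matrixSize[1] - 1) / 2
  cy <- geom@pose[2, 4] + (geom@fovMm[2] / geom@matrixSize[2]) *
    (geom@matrixSize[2] - 1) / 2
  X <- matrix(cen$x - cx, geom@matrixSize[1], geom@matrixSize[2])
  Y <- matrix(cen$y - cy, geom@matrixSize[1], geom@matrixSize[2],
              byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  keep <- r >= radiusMm[1] & r <= radiusMm[2]
  if (!is.null(fractions))
    keep <- keep & is.finite(fCSF(fractions)) & fCSF(fractions) <= csfMax
  list(anterior = keep & Y > 0 & abs(Y) > abs(X),
       posterior = keep & Y < 0 & abs(Y) > abs(X),
       left = keep & X < 0 & abs(X) >= abs(Y),
       right = keep & X > 0 & abs(X) >= abs(Y))
}

#' Summarize concentrations per ROI
#'
#' NaN-aware mean and sample SD of each metabolite map over each ROI,
#' restricted to valid voxels.
#'
#' @param conc A [ConcentrationResult-class].
#' @param rois Named list of logical matrices on the MRSI grid.
#' @param scale "molal" or "molar".
#' @return data.frame with roi, metabolite, mean, sd, n.
#' @examples
#' # roiSummarize(result, defaultRois(geom, fractions))
#' @export
roiSummarize <- function(conc, rois, scale = c("molal", "molar")) {
  scale <- match.arg(scale)
  maps <- if (scale == "molal") molalMaps(conc) else molarMaps(conc)
  ok <- validMask(conc)
  rows <- list()
  for (rn in names(rois)) {
    for (mn in names(maps)) {
      v <- maps[[mn]][rois[[rn]] & ok]
      v <- v[is.finite(v)]
      if (!length(v))
        stop("ROI '", rn, "' is empty after masking")
      rows[[length(rows) + 1L]] <- data.frame(
        roi = rn, metabolite = mn, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bland-Altman agreement between two methods
#'
#' Differences `d = a - b` over paired measurements: bias = mean(d), sd =
#' sample SD(d), limits of agreement bias +/- 1.96 sd. Percent forms are
#' normalized by the grand mean of the pair means `(a + b)/2`.
#'
#' @param a,b Paired numeric vectors (same length, >= 2 valid pairs).
#' @return A list of class "AgreementReport": `bias`, `sd`, `loa`
#'   (length 2), `n`, `pctBias`, `pctSd`, `pctLoa`, `meanOfMeans`, `order`.
#' @examples
#' blandAltman(c(10, 12, 14), c(10.5, 11.5, 14.2))
#' @export
blandAltman <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("need at least 2 valid pairs")
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  mm <- mean((a + b) / 2)
  out <- list(bias = bias, sd = sdd,
              loa = c(bias - 1.96 * sdd, bias + 1.96 * sdd),
              n = length(a),
              pctBias = 100 * bias / mm, pctSd = 100 * sdd / mm,
              pctLoa = 100 * (bias + c(-1.96, 1.96) * sdd) / mm,
              meanOfMeans = mm, order = "first minus second")
  class(out) <- c("AgreementReport", "list")
  out
}

#' @export
print.AgreementReport <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d, %s):\n  bias %.4g (%.2f%% of mean), SD %.4g (%.2f%%)\n  limits of agreement [%.4g, %.4g]\n",
    x$n, x$order, x$bias, x$pctBias, x$sd, x$pctSd, x$loa[1], x$loa[2]))
  invisible(x)
}

#' Bland-Altman scatter plot
#'
#' @param x An "AgreementReport" (for the reference lines) created from the
#'   same pairs.
#' @param a,b The paired values.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL. Draws on the active device.
#' @export
plotBlandAltman <- function(x, a, b, ...) {
  ok <- is.finite(a) & is.finite(b)
  m <- (a[ok] + b[ok]) / 2
  d <- a[ok] - b[ok]
  graphics::plot(m, d, xlab = "mean of methods", ylab = "difference",
                 ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2),
                   col = c("black", "grey40", "grey40"))
  invisible(NULL)
}
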