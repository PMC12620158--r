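# Affine helpers. The package assumes co-registered, axis-aligned maps:
# rotations are rejected early rather than silently mishandled.

#' Build an axis-aligned voxel-to-world affine
#'
#' @param voxelMm Voxel edge lengths (length 3) in mm.
#' @param originMm World position of the center of voxel (0,0,0).
#' @return 4x4 numeric matrix.
#' @keywords internal
affineFromSpacing <- function(voxelMm, originMm = c(0, 0, 0)) {
  a <- diag(4)
  a[1, 1] <- voxelMm[1]; a[2, 2] <- voxelMm[2]; a[3, 3] <- voxelMm[3]
  a[1:3, 4] <- originMm
  a
}

# voxel edge lengths; errors on rotated affines (inputs must be axis-aligned)
affineSpacing <- function(affine) {
  r <- affine[1:3, 1:3]
  offdiag <- r; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-6 * max(abs(diag(r))))
    stop("map affine is not axis-aligned; co-register/resample inputs first")
  sp <- diag(r)
  if (any(sp <= 0))
    stop("negative or zero voxel spacing; reorient maps to positive axes")
  sp
}

# world extent [start, end] (outer voxel edges) along each axis
mapExtent <- function(map) {
  sp <- affineSpacing(mapAffine(map))
  o <- mapAffine(map)[1:3, 4]
  d <- dim(mapValues(map))
  rbind(start = o - sp / 2, end = o + (d - 0.5) * sp)
}
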