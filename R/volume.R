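#' CT volume container
#'
#' A 3D grid of Hounsfield units with voxel spacing and world origin. Array
#' index `[i, j, k]` maps to world position `origin + (c(i,j,k) - 1) * spacing`
#' (voxel centres), axes ordered x, y, z.
#'
#' @param data 3D numeric array (HU).
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm, all `> 0`.
#' @param origin world position of voxel `[1, 1, 1]` in mm.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values")
  if (length(origin) != 3L) stop("origin must have three components")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

## World-coordinate axes of the grid (voxel centres).
.vol_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Trilinear interpolation of a CT volume at world points
#'
#' @param vol a [ct_volume].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return numeric vector of interpolated HU; `NA` for points outside the
#'   voxel-centre bounding box.
#' @export
interp_trilinear <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  d <- dim(vol$data)
  # continuous voxel coordinates, 1-based
  u <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  i0 <- floor(u)
  f <- u - i0
  ok <- u[, 1] >= 1 & u[, 1] <= d[1] & u[, 2] >= 1 & u[, 2] <= d[2] &
    u[, 3] >= 1 & u[, 3] <= d[3]
  # clamp the upper cell so points exactly on the far face interpolate
  i0 <- pmin(pmax(i0, 1), matrix(rep(d - 1L, each = nrow(u)), ncol = 3))
  f <- u - i0
  out <- rep(NA_real_, nrow(u))
  if (any(ok)) {
    ii <- i0[ok, , drop = FALSE]
    ff <- f[ok, , drop = FALSE]
    lin <- function(dx, dy, dz) {
      vol$data[cbind(ii[, 1] + dx, ii[, 2] + dy, ii[, 3] + dz)]
    }
    wx <- ff[, 1]; wy <- ff[, 2]; wz <- ff[, 3]
    out[ok] <-
      lin(0, 0, 0) * (1 - wx) * (1 - wy) * (1 - wz) +
      lin(1, 0, 0) * wx * (1 - wy) * (1 - wz) +
      lin(0, 1, 0) * (1 - wx) * wy * (1 - wz) +
      lin(1, 1, 0) * wx * wy * (1 - wz) +
      lin(0, 0, 1) * (1 - wx) * (1 - wy) * wz +
      lin(1, 0, 1) * wx * (1 - wy) * wz +
      lin(0, 1, 1) * (1 - wx) * wy * wz +
      lin(1, 1, 1) * wx * wy * wz
  }
  out
}

#' Write / read a CT volume as NIfTI
#'
#' The affine carries the voxel spacing and origin.
#'
#' @param vol a [ct_volume].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns a [ct_volume].
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3])
}
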