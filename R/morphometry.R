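#' Cross-sectional centroids of a diaphysis
#'
#' Area centroids of the cross-section contours at equally spaced transverse
#' planes within the diaphysis (30-70% of the bone's long-axis extent in the
#' given frame): 10 planes dividing the femoral diaphysis into 11 equal
#' sections, 12 planes dividing the tibial diaphysis into 13.
#'
#' @param mesh a [cbt_mesh].
#' @param frame a [tibial_cs] (or femoral frame of the same class) in which
#'   the planes are taken perpendicular to the z axis.
#' @param bone `"tibia"` (12 centroids) or `"femur"` (10 centroids).
#' @param diaphysis_fracs extent of the diaphysis as fractions of the mesh z
#'   range in the frame.
#' @return n x 3 matrix of centroids in frame coordinates, ordered distal to
#'   proximal.
#' @export
compute_section_centroids <- function(mesh, frame,
                                      bone = c("tibia", "femur"),
                                      diaphysis_fracs = c(0.30, 0.70)) {
  bone <- match.arg(bone)
  n_planes <- if (bone == "femur") 10L else 12L
  v <- to_cs(mesh$vertices, frame)
  zr <- range(v[, 3])
  z0 <- zr[1] + diaphysis_fracs[1] * diff(zr)
  z1 <- zr[1] + diaphysis_fracs[2] * diff(zr)
  # planes divide the diaphysis into n_planes + 1 equal sections
  fr <- seq_len(n_planes) / (n_planes + 1)
  zp <- z0 + fr * (z1 - z0)
  mesh_f <- mesh
  mesh_f$vertices <- v
  out <- matrix(NA_real_, nrow = n_planes, ncol = 3)
  for (i in seq_len(n_planes)) {
    pts <- .mesh_plane_points(mesh_f, c(0, 0, 1), zp[i])
    if (is.null(pts) || nrow(pts) < 3L)
      stop("section plane ", i, " (z = ", round(zp[i], 1),
           " mm) does not intersect the mesh")
    out[i, ] <- c(.polygon_centroid(pts[, 1:2, drop = FALSE]), zp[i])
  }
  colnames(out) <- c("x", "y", "z")
  out
}

## Area centroid of a planar point loop: points ordered by angle around
## their mean (sections here are star-shaped), then the shoelace centroid.
.polygon_centroid <- function(p) {
  cx <- mean(p[, 1]); cy <- mean(p[, 2])
  o <- order(atan2(p[, 2] - cy, p[, 1] - cx))
  x <- p[o, 1]; y <- p[o, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(cx, cy))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Total-least-squares anatomical axis through section centroids
#'
#' The 3D regression line minimizing summed squared orthogonal distances:
#' the first principal direction through the centroid mean.
#'
#' @param centroids n x 3 matrix, `n >= 2`, not all coincident.
#' @return list of class `anatomical_axis`: `point` (mean), `direction`
#'   (unit), `rms_residual` (mm), `n_centroids`.
#' @export
fit_anatomical_axis <- function(centroids) {
  centroids <- matrix(centroids, ncol = 3)
  if (nrow(centroids) < 2L) stop("axis fit needs at least 2 centroids")
  ctr <- colMeans(centroids)
  X <- sweep(centroids, 2, ctr)
  if (max(abs(X)) < 1e-12) stop("all centroids coincide; no axis defined")
  sv <- svd(X)
  dir <- sv$v[, 1]
  perp <- X - (X %*% dir) %*% t(dir)
  structure(list(point = ctr, direction = as.numeric(dir),
                 rms_residual = sqrt(mean(rowSums(perp^2))),
                 n_centroids = nrow(centroids)),
            class = "anatomical_axis")
}

#' Femorotibial angle from the two anatomical axes
#'
#' Both axis directions are projected onto the coronal (xz) plane of the
#' femoral coordinate system; the femoral direction is oriented proximally
#' and the tibial direction distally. The FTA is anchored at 180 degrees for
#' a collinear limb and grows with varus: the signed coronal deviation of
#' the distal tibial direction from the prolonged femoral axis is positive
#' when the distal tibia deviates toward the body midline.
#'
#' @param femoral_axis,tibial_axis lists with `point` and `direction`
#'   (world coordinates), e.g. from [fit_anatomical_axis()].
#' @param femoral_frame the femoral coordinate system (a [tibial_cs]-class
#'   frame: x right, y anterior, z superior).
#' @param side `"right"` or `"left"`.
#' @return list of class `fta_result`: `fta` (degrees) and
#'   `varus_deviation` (`fta - 180`).
#' @export
compute_fta <- function(femoral_axis, tibial_axis, femoral_frame,
                        side = c("right", "left")) {
  side <- match.arg(side)
  R <- cbind(femoral_frame$x_axis, femoral_frame$y_axis,
             femoral_frame$z_axis)
  df <- as.numeric(t(R) %*% femoral_axis$direction)
  dt <- as.numeric(t(R) %*% tibial_axis$direction)
  # coronal projections (x, z)
  u <- c(df[1], df[3])
  v <- c(dt[1], dt[3])
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9)
    stop("an axis is orthogonal to the coronal plane; FTA undefined")
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  if (u[2] < 0) u <- -u       # femoral direction proximal
  if (v[2] > 0) v <- -v       # tibial direction distal
  w <- -u                      # prolonged femoral axis, distal
  delta <- atan2(w[1] * v[2] - w[2] * v[1], sum(w * v)) * 180 / pi
  varus <- if (side == "right") -delta else delta
  structure(list(fta = 180 + varus, varus_deviation = varus),
            class = "fta_result")
}

#' Least-squares plane through digitized plateau points
#'
#' The plane minimizing summed squared orthogonal distances (smallest
#' principal component of the centred points).
#'
#' @param points n x 3 matrix, `n >= 3`, not collinear.
#' @return list of class `mct_plane`: `normal` (unit), `offset`
#'   (`normal . p = offset`), `centroid`, `fit_rms` (mm).
#' @export
fit_mct_plane <- function(points) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("points are collinear; no unique plane")
  normal <- sv$v[, 3]
  d <- X %*% normal
  structure(list(normal = as.numeric(normal),
                 offset = sum(normal * ctr), centroid = ctr,
                 fit_rms = sqrt(mean(d^2))),
            class = "mct_plane")
}

#' Coronal inclination of the medial tibial plateau
#'
#' The minimum 3D angle between the tibial x-axis and the line in which the
#' plateau plane crosses the tibial coronal (xz) plane. A horizontal plateau
#' gives 0 degrees; a plane `z = c + b*x` in the tibial frame gives
#' `atan(|b|)`. A sagittal (y) tilt of the plateau leaves the angle
#' unchanged.
#'
#' @param plane an `mct_plane` (world coordinates).
#' @param tibial_cs a [tibial_cs].
#' @return angle in degrees, in \[0, 90\].
#' @export
mct_coronal_angle <- function(plane, tibial_cs) {
  R <- cbind(tibial_cs$x_axis, tibial_cs$y_axis, tibial_cs$z_axis)
  n_cs <- as.numeric(t(R) %*% plane$normal)
  d <- .cross3(n_cs, c(0, 1, 0))   # crossing line with the xz-plane
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9)
    stop("plateau plane is parallel to the coronal plane; ",
         "no unique crossing line")
  acos(min(abs(d[1]) / nd, 1)) * 180 / pi
}
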