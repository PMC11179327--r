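#' Anatomical tibial coordinate system
#'
#' Origin plus a right-handed orthonormal triad: x positive right,
#' y positive anterior, z positive superior.
#'
#' @param origin 3D point (mm).
#' @param x_axis,y_axis,z_axis unit vectors; must be pairwise orthogonal and
#'   right-handed (`x` cross `y` equals `z`).
#' @return object of class `tibial_cs`.
#' @export
tibial_cs <- function(origin, x_axis, y_axis, z_axis) {
  R <- cbind(x_axis, y_axis, z_axis)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("axes must be orthonormal")
  if (sum(.cross3(x_axis, y_axis) * z_axis) < 0)
    stop("axes must be right-handed (x cross y = z)")
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis), z_axis = as.numeric(z_axis)),
            class = "tibial_cs")
}

#' @export
print.tibial_cs <- function(x, ...) {
  cat("<tibial_cs> origin", paste(signif(x$origin, 4), collapse = ", "), "\n")
  invisible(x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Algebraic least-squares circle fit of 2D section points
#'
#' Kasa fit: linear least squares of `x^2 + y^2` on `(2x, 2y, 1)`. Used for
#' the two diaphyseal cross-sections whose centres define the temporal
#' z-axis.
#'
#' @param points n x 2 matrix (mm), `n >= 3`, not collinear.
#' @return list with `center` (length 2), `radius` (mm) and `residual`
#'   (RMS radial misfit, mm).
#' @export
fit_section_circle <- function(points) {
  points <- matrix(points, ncol = 2)
  if (nrow(points) < 3L) stop("circle fit needs at least 3 points")
  A <- cbind(2 * points[, 1], 2 * points[, 2], 1)
  b <- points[, 1]^2 + points[, 2]^2
  qa <- qr(A)
  if (qa$rank < 3L) stop("circle fit needs non-collinear points")
  coef <- qr.coef(qa, b)
  center <- coef[1:2]
  radius <- sqrt(coef[3] + sum(center^2))
  r_i <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  list(center = unname(center), radius = unname(radius),
       residual = sqrt(mean((r_i - radius)^2)))
}

## Cross-section contour of a mesh with the plane {p : n.p = d}; returns the
## intersection points of mesh edges with the plane.
.mesh_plane_points <- function(mesh, normal, d) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- v %*% normal - d
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  sa <- s[e[, 1]]; sb <- s[e[, 2]]
  hit <- (sa <= 0 & sb > 0) | (sb <= 0 & sa > 0)
  if (!any(hit)) return(NULL)
  ta <- sa[hit] / (sa[hit] - sb[hit])
  v[e[hit, 1], , drop = FALSE] +
    ta * (v[e[hit, 2], , drop = FALSE] - v[e[hit, 1], , drop = FALSE])
}

#' Build the anatomical tibial coordinate system
#'
#' The construction: (1) the temporal z-axis joins the centres of
#' least-squares circles fitted to two transverse diaphyseal cross-sections
#' (default at 30% and 70% of the mesh z-extent), oriented superiorly;
#' (2) the y-axis is the line from the PCL attachment to the medial edge of
#' the tibial tuberosity, projected orthogonal to the temporal z-axis
#' (positive anterior); (3) the triad is completed right-handed with
#' x positive right and the true z-axis positive superior
#' (`x = y` cross `temporal z`, `z = x` cross `y`, `y` re-derived), and
#' (4) the origin is the intersection of the true z-axis with the distal
#' articular surface patch.
#'
#' @param mesh a [cbt_mesh] spanning the two section planes.
#' @param landmarks named list with `pcl_attachment`,
#'   `tuberosity_medial_edge`, `eminence_medial`, `eminence_lateral`,
#'   `talar_dome_medial`, `talar_dome_lateral` (3D points, mm) and
#'   `distal_articular_surface` (list with `vertices`, `faces`).
#' @param section_fracs fractions of the mesh long-axis extent where the two
#'   circle-fit sections are taken.
#' @param slab half-thickness (mm) of the slab of intersection used for each
#'   section.
#' @return a [tibial_cs].
#' @export
build_tibial_cs <- function(mesh, landmarks, section_fracs = c(0.3, 0.7),
                            slab = 2) {
  lm <- landmarks
  needed <- c("pcl_attachment", "tuberosity_medial_edge", "eminence_medial",
              "eminence_lateral", "talar_dome_medial", "talar_dome_lateral",
              "distal_articular_surface")
  if (!all(needed %in% names(lm)))
    stop("missing landmarks: ", paste(setdiff(needed, names(lm)),
                                      collapse = ", "))

  # initial long axis from the vertex cloud, oriented distal -> proximal
  pc <- stats::prcomp(mesh$vertices, center = TRUE)
  axis0 <- pc$rotation[, 1]
  prox <- (lm$eminence_medial + lm$eminence_lateral) / 2
  dist_ref <- (lm$talar_dome_medial + lm$talar_dome_lateral) / 2
  if (sum(axis0 * (prox - dist_ref)) < 0) axis0 <- -axis0

  s <- mesh$vertices %*% axis0
  centers <- lapply(section_fracs, function(fr) {
    d <- min(s) + fr * (max(s) - min(s))
    pts <- .mesh_plane_points(mesh, axis0, d)
    if (is.null(pts) || nrow(pts) < 3L)
      stop("section plane at fraction ", fr, " does not intersect the mesh")
    # 2D coordinates in the plane
    basis <- .plane_basis(axis0)
    p2 <- pts %*% basis
    circ <- fit_section_circle(p2)
    basis %*% circ$center + axis0 * d
  })
  tz <- .unit(as.numeric(centers[[2]] - centers[[1]]))
  if (sum(tz * (prox - dist_ref)) < 0) tz <- -tz

  y_raw <- lm$tuberosity_medial_edge - lm$pcl_attachment
  y_axis <- y_raw - sum(y_raw * tz) * tz
  if (sqrt(sum(y_axis^2)) < 1e-9)
    stop("degenerate y-axis: PCL attachment and tuberosity landmarks ",
         "coincide or align with the temporal z-axis")
  y_axis <- .unit(y_axis)

  # canonical right-handed completion (x right, z superior)
  x_axis <- .unit(.cross3(y_axis, tz))
  z_axis <- .unit(.cross3(x_axis, y_axis))
  y_axis <- .cross3(z_axis, x_axis)

  origin <- .ray_patch_intersection(
    point = as.numeric((centers[[1]] + centers[[2]])) / 2,
    direction = -z_axis,
    patch = lm$distal_articular_surface)
  if (is.null(origin))
    stop("the true z-axis does not intersect the distal articular surface")

  tibial_cs(origin = origin, x_axis = x_axis, y_axis = y_axis,
            z_axis = z_axis)
}

## Orthonormal in-plane basis for a plane with the given normal.
.plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross3(normal, a))
  v <- .cross3(normal, u)
  cbind(u, v)
}

## Moeller-Trumbore ray/triangle intersection over a patch; returns the most
## distal (largest ray parameter) hit, or NULL.
.ray_patch_intersection <- function(point, direction, patch) {
  v <- patch$vertices
  f <- patch$faces
  best <- NULL; best_t <- -Inf
  for (i in seq_len(nrow(f))) {
    p0 <- v[f[i, 1], ]; p1 <- v[f[i, 2], ]; p2 <- v[f[i, 3], ]
    e1 <- p1 - p0; e2 <- p2 - p0
    h <- .cross3(direction, e2)
    a <- sum(e1 * h)
    if (abs(a) < 1e-12) next
    s <- point - p0
    u <- sum(s * h) / a
    if (u < -1e-9 || u > 1 + 1e-9) next
    q <- .cross3(s, e1)
    w <- sum(direction * q) / a
    if (w < -1e-9 || u + w > 1 + 1e-9) next
    tt <- sum(e2 * q) / a
    if (tt > 0 && tt > best_t) {
      best_t <- tt
      best <- point + tt * direction
    }
  }
  best
}

#' Transform points into (or out of) a tibial coordinate system
#'
#' Rigid transform `p' = R^T (p - origin)` with `R = [x y z]`;
#' `from_cs` is the exact inverse, so the round trip is the identity.
#'
#' @param points n x 3 matrix or length-3 vector (mm).
#' @param cs a [tibial_cs].
#' @return transformed points, same shape as input.
#' @export
to_cs <- function(points, cs) {
  vec <- is.null(dim(points))
  points <- matrix(points, ncol = 3)
  R <- cbind(cs$x_axis, cs$y_axis, cs$z_axis)
  out <- sweep(points, 2, cs$origin, "-") %*% R
  if (vec) as.numeric(out) else out
}

#' @rdname to_cs
#' @export
from_cs <- function(points, cs) {
  vec <- is.null(dim(points))
  points <- matrix(points, ncol = 3)
  R <- cbind(cs$x_axis, cs$y_axis, cs$z_axis)
  out <- sweep(points %*% t(R), 2, cs$origin, "+")
  if (vec) as.numeric(out) else out
}
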