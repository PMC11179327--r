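#' Specify a synthetic tibia phantom
#'
#' The phantom is a tapered tube aligned with the z axis of its own frame
#' (x positive right, y anterior, z superior; distal articular surface at
#' z = 0, plateau at z = `tibial_length`), with a cortical shell whose
#' thickness varies over height and azimuth between three density levels
#' (soft tissue, cortex, trabecular bone). Imaging is emulated by blurring
#' the density model with an isotropic Gaussian point-spread function and
#' adding voxel noise.
#'
#' @param tibial_length tibial length L in mm (eminence midpoint to talar
#'   midpoint).
#' @param outer_radius function of height fraction `h` in \[0, 1\] returning
#'   the periosteal radius (mm); vectorised.
#' @param thickness_field function of `(h, theta)` returning the true
#'   cortical thickness (mm); values must stay inside (0.5, 12) mm and below
#'   the local radius; vectorised.
#' @param densities `c(y0, y1, y2)` in HU: soft tissue, cortical, trabecular;
#'   the cortex must be the densest (`y1 > y2 > y0`).
#' @param psf_sigma Gaussian blur width sigma (mm), `> 0`.
#' @param voxel_spacing `c(dx, dy, dz)` in mm (clinical-CT anisotropy by
#'   default).
#' @param noise_sd additive Gaussian voxel noise (HU).
#' @param varus_angle coronal femur-tibia deviation (degrees); positive =
#'   varus, so the true FTA is `180 + varus_angle`.
#' @param mct_coronal_slope coronal slope (tangent) of the intended medial
#'   plateau plane; the true MCT coronal angle is `atan(mct_coronal_slope)`.
#' @param side `"right"` or `"left"`.
#' @param seed integer seed for the voxel noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(tibial_length = 350,
                         outer_radius = function(h)
                           11 + 12 * pmax(h - 0.8, 0)^2 / 0.04 +
                           6 * pmax(0.15 - h, 0)^2 / 0.0225,
                         thickness_field = function(h, theta)
                           5 + cos(theta) * sin(pi * pmin(pmax(h, 0), 1)),
                         densities = c(0, 1200, 300),
                         psf_sigma = 0.9,
                         voxel_spacing = c(0.7, 0.7, 1.0),
                         noise_sd = 20,
                         varus_angle = 7,
                         mct_coronal_slope = tan(12.2 * pi / 180),
                         side = c("right", "left"),
                         seed = 1L) {
  structure(list(tibial_length = tibial_length, outer_radius = outer_radius,
                 thickness_field = thickness_field, densities = densities,
                 psf_sigma = psf_sigma, voxel_spacing = voxel_spacing,
                 noise_sd = noise_sd, varus_angle = varus_angle,
                 mct_coronal_slope = mct_coronal_slope,
                 side = match.arg(side), seed = as.integer(seed)),
            class = "phantom_spec")
}

.validate_phantom_spec <- function(spec) {
  if (!is.numeric(spec$tibial_length) || spec$tibial_length <= 0)
    stop("invalid phantom spec: tibial_length must be > 0")
  if (length(spec$densities) != 3L ||
      !(spec$densities[2] > spec$densities[3] &&
          spec$densities[3] > spec$densities[1]))
    stop("invalid phantom spec: densities must satisfy y1 > y2 > y0 ",
         "(cortex densest)")
  if (spec$psf_sigma <= 0)
    stop("invalid phantom spec: psf_sigma must be > 0")
  if (any(spec$voxel_spacing <= 0))
    stop("invalid phantom spec: voxel_spacing must be all > 0")
  if (spec$noise_sd < 0)
    stop("invalid phantom spec: noise_sd must be >= 0")
  h <- seq(0.02, 0.98, length.out = 49)
  th <- seq(-pi, pi, length.out = 64)
  grid <- expand.grid(h = h, theta = th)
  tv <- spec$thickness_field(grid$h, grid$theta)
  if (any(!is.finite(tv)) || any(tv <= 0.5) || any(tv >= 12))
    stop("invalid phantom spec: thickness_field must stay inside (0.5, 12) mm")
  rv <- spec$outer_radius(grid$h)
  if (any(rv - tv < 1))
    stop("invalid phantom spec: thickness_field exceeds the outer radius ",
         "(inner radius would drop below 1 mm)")
  invisible(spec)
}

## Femoral coordinate frame (columns = axes in phantom/world coordinates)
## realising a given coronal varus deviation: a rotation about the anterior
## (y) axis so that the tibia's distal direction deviates medially in
## femoral coordinates.
.femoral_frame_for_varus <- function(varus_deg, side = "right") {
  a <- varus_deg * pi / 180 * (if (side == "right") 1 else -1)
  cbind(x = c(cos(a), 0, sin(a)),
        y = c(0, 1, 0),
        z = c(-sin(a), 0, cos(a)))
}

#' Generate a synthetic tibia CT volume with ground truth
#'
#' Voxel values follow the three-level density model blurred with the
#' Gaussian point-spread function: for a voxel at radius `r` from the shaft
#' axis at height fraction `h` with local outer radius `R` and true
#' thickness `t`, the noiseless value is the closed-form blurred two-edge
#' profile evaluated along the surface normal,
#' `y0 + (y1-y0)*pnorm((R-r)/sigma) + (y2-y1)*pnorm((R-t-r)/sigma)`
#' (isotropic 3D blur of a locally planar interface equals 1D blur along its
#' normal). I.i.d. Gaussian noise is added with the spec's seed, so identical
#' specs give bit-identical volumes.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (a [ct_volume]) and `truth` (class
#'   `cbt_ground_truth`): landmark coordinates, the true thickness field
#'   evaluator `true_thickness_at(points)`, the true tibial frame, the
#'   femoral frame/axis realising the requested varus, `true_fta`, and
#'   `true_mct_angle`.
#' @export
generate_tibia_phantom <- function(spec = phantom_spec()) {
  .validate_phantom_spec(spec)
  L <- spec$tibial_length
  y0 <- spec$densities[1]; y1 <- spec$densities[2]; y2 <- spec$densities[3]
  sg <- spec$psf_sigma
  sp <- spec$voxel_spacing

  h_probe <- seq(0, 1, length.out = 201)
  rmax <- max(spec$outer_radius(h_probe))
  half_xy <- rmax + 12           # room for outside-bone profile sampling
  # symmetric grids with a voxel centre on the shaft axis
  nx <- 2L * ceiling(half_xy / sp[1]) + 1L
  ny <- 2L * ceiling(half_xy / sp[2]) + 1L
  xs <- (seq_len(nx) - (nx + 1) / 2) * sp[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * sp[2]
  zs <- seq(-4, L + 4, by = sp[3])

  X <- matrix(xs, nrow = length(xs), ncol = length(ys))
  Y <- matrix(ys, nrow = length(xs), ncol = length(ys), byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)

  data <- array(y0, dim = c(length(xs), length(ys), length(zs)))
  inside <- which(zs >= 0 & zs <= L)
  for (k in inside) {
    h <- zs[k] / L
    R <- spec$outer_radius(h)
    tt <- spec$thickness_field(h, theta)
    data[, , k] <- y0 + (y1 - y0) * stats::pnorm((R - r) / sg) +
      (y2 - y1) * stats::pnorm((R - tt - r) / sg)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    data <- data + array(stats::rnorm(length(data), sd = spec$noise_sd),
                         dim = dim(data))
  }
  vol <- ct_volume(data, spacing = sp, origin = c(xs[1], ys[1], zs[1]))

  med <- if (spec$side == "right") -1 else 1   # medial direction along x
  landmarks <- list(
    pcl_attachment = c(0, -14, L - 8),
    tuberosity_medial_edge = c(0, 16, L - 45),
    eminence_medial = c(8 * med, 0, L),
    eminence_lateral = c(-8 * med, 0, L),
    talar_dome_medial = c(9 * med, 0, 0),
    talar_dome_lateral = c(-9 * med, 0, 0),
    distal_articular_surface = .disc_patch(c(0, 0, 0), radius = 12, n = 10)
  )

  true_cs <- tibial_cs(origin = c(0, 0, 0),
                       x_axis = c(1, 0, 0), y_axis = c(0, 1, 0),
                       z_axis = c(0, 0, 1))
  fem_frame <- .femoral_frame_for_varus(spec$varus_angle, spec$side)
  knee_center <- c(0, 0, L + 2)
  truth <- structure(list(
    true_thickness_at = function(points) {
      points <- matrix(points, ncol = 3)
      h <- points[, 3] / L
      spec$thickness_field(h, atan2(points[, 2], points[, 1]))
    },
    landmarks = landmarks,
    true_tibial_cs = true_cs,
    femoral_cs = tibial_cs(origin = knee_center,
                           x_axis = fem_frame[, 1], y_axis = fem_frame[, 2],
                           z_axis = fem_frame[, 3]),
    femoral_axis = list(point = knee_center, direction = fem_frame[, 3]),
    true_fta = 180 + spec$varus_angle,
    true_mct_angle = atan(abs(spec$mct_coronal_slope)) * 180 / pi,
    side = spec$side,
    tibial_length = L,
    spec = spec
  ), class = "cbt_ground_truth")

  list(volume = vol, truth = truth)
}

## Small triangulated disc used as the distal articular surface patch.
.disc_patch <- function(center, radius, n = 10, normal_tilt = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring <- cbind(center[1] + radius * cos(th),
                center[2] + radius * sin(th),
                center[3] + normal_tilt[1] * radius * cos(th) +
                  normal_tilt[2] * radius * sin(th))
  vertices <- rbind(center, ring)
  faces <- cbind(1L, 1L + seq_len(n), 1L + c(seq_len(n)[-1], 1L))
  list(vertices = vertices, faces = faces)
}

#' Generate digitized points on the medial tibial plateau
#'
#' Points are scattered on the medial-plateau footprint of the plane
#' `z = offset + coronal_slope * x + sagittal_slope * y` (tibial-frame
#' coordinates), optionally perturbed in z by Gaussian noise — the synthetic
#' counterpart of manually digitizing the medial plateau surface.
#'
#' @param coronal_slope slope of the plane along x (tan of the coronal
#'   angle).
#' @param sagittal_slope slope along y.
#' @param n number of points, `>= 3` (default 8).
#' @param noise_sd Gaussian z perturbation (mm).
#' @param seed integer seed.
#' @param side `"right"` or `"left"`; fixes which x half-plane is medial.
#' @param offset plane height at the frame origin (mm).
#' @param jitter in-plane digitization scatter (mm, uniform) around the
#'   nominal sites.
#' @details The footprint emulates how a plateau is digitized in practice:
#'   the points run anterior-to-posterior along the outer (medial) and inner
#'   rims of the compartment, avoiding its concave centre, which also
#'   maximises the baseline of the plane fit.
#' @return n x 3 matrix of tibial-frame points.
#' @export
generate_mct_points <- function(coronal_slope, sagittal_slope = 0, n = 8,
                                noise_sd = 0, seed = NULL,
                                side = c("right", "left"), offset = 0,
                                jitter = 1) {
  side <- match.arg(side)
  if (n < 3) stop("at least 3 points are required to define a plane")
  if (!is.null(seed)) set.seed(seed)
  med <- if (side == "right") -1 else 1
  n_out <- ceiling(n / 2)
  n_in <- n - n_out
  x <- med * c(rep(25, n_out), rep(6, n_in))
  y <- c(seq(-12, 12, length.out = n_out),
         seq(-12, 12, length.out = max(n_in, 2))[seq_len(n_in)])
  if (jitter > 0) {
    x <- x + stats::runif(n, -jitter, jitter)
    y <- y + stats::runif(n, -jitter, jitter)
  }
  z <- offset + coronal_slope * x + sagittal_slope * y
  if (noise_sd > 0) z <- z + stats::rnorm(n, sd = noise_sd)
  cbind(x = x, y = y, z = z)
}
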