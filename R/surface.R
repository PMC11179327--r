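#' Surface mesh container
#'
#' @param vertices n x 3 matrix of mm coordinates.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param normals n x 3 matrix of outward unit normals.
#' @return object of class `cbt_mesh`.
#' @export
cbt_mesh <- function(vertices, faces, normals) {
  vertices <- matrix(vertices, ncol = 3)
  normals <- matrix(normals, ncol = 3)
  if (nrow(vertices) != nrow(normals)) stop("one normal per vertex required")
  nl <- sqrt(rowSums(normals^2))
  if (any(abs(nl - 1) > 1e-6)) normals <- normals / nl
  structure(list(vertices = vertices,
                 faces = matrix(as.integer(faces), ncol = 3),
                 normals = normals),
            class = "cbt_mesh")
}

#' @export
print.cbt_mesh <- function(x, ...) {
  cat("<cbt_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

#' Extract the periosteal surface from a CT volume
#'
#' Per-slice sub-pixel iso-contours at the given threshold
#' (largest contour of each transverse slice, linear interpolation between
#' voxel centres), resampled to a fixed number of azimuthal points and
#' stacked into a ring mesh. Per-vertex normals are the in-plane outward
#' perpendiculars to the contour, which is how the normals guide the
#' in-plane thickness profiles.
#'
#' @param volume a [ct_volume].
#' @param threshold iso-level in HU; `NULL` picks the midpoint of the
#'   background and cortical levels estimated from the volume histogram.
#' @param slice_step use every `slice_step`-th slice (controls vertex
#'   density along z).
#' @param n_azimuth number of contour points per slice.
#' @param z_range optional `c(zmin, zmax)` in mm restricting the slices used.
#' @return a [cbt_mesh].
#' @export
extract_surface <- function(volume, threshold = NULL, slice_step = 2L,
                            n_azimuth = 32L, z_range = NULL) {
  axes <- .vol_axes(volume)
  if (is.null(threshold)) {
    q <- stats::quantile(volume$data, c(0.05, 0.999))
    threshold <- mean(q)   # midpoint of background and densest material
  }
  if (max(volume$data) <= threshold)
    stop("empty segmentation: no voxel above the threshold ",
         signif(threshold, 4), " HU")
  ks <- seq(1L, length(axes[[3]]), by = slice_step)
  if (!is.null(z_range))
    ks <- ks[axes[[3]][ks] >= z_range[1] & axes[[3]][ks] <= z_range[2]]

  rings <- list()
  zs <- numeric(0)
  for (k in ks) {
    cl <- grDevices::contourLines(axes[[1]], axes[[2]],
                                  volume$data[, , k], levels = threshold)
    if (length(cl) == 0L) next
    len <- vapply(cl, function(cc) length(cc$x), 0L)
    cc <- cl[[which.max(len)]]
    if (length(cc$x) < 8L) next
    ring <- .resample_ring(cc$x, cc$y, n_azimuth)
    rings[[length(rings) + 1L]] <- ring
    zs <- c(zs, axes[[3]][k])
  }
  if (length(rings) < 2L)
    stop("surface extraction found fewer than two usable slice contours")

  m <- n_azimuth
  s <- length(rings)
  vertices <- matrix(0, nrow = s * m, ncol = 3)
  normals <- matrix(0, nrow = s * m, ncol = 3)
  for (i in seq_len(s)) {
    idx <- (i - 1L) * m + seq_len(m)
    vertices[idx, 1:2] <- rings[[i]]
    vertices[idx, 3] <- zs[i]
    normals[idx, 1:2] <- .ring_normals(rings[[i]])
  }
  faces <- matrix(0L, nrow = 2L * (s - 1L) * m, ncol = 3)
  fi <- 0L
  for (i in seq_len(s - 1L)) {
    a <- (i - 1L) * m
    b <- i * m
    for (j in seq_len(m)) {
      j2 <- if (j == m) 1L else j + 1L
      faces[fi + 1L, ] <- c(a + j, a + j2, b + j)
      faces[fi + 2L, ] <- c(a + j2, b + j2, b + j)
      fi <- fi + 2L
    }
  }
  cbt_mesh(vertices, faces, normals)
}

## Resample a closed contour to n points at equal angles around its centroid
## (sections are star-shaped tubes here), interpolating radius over angle.
.resample_ring <- function(x, y, n) {
  cx <- mean(x); cy <- mean(y)
  th <- atan2(y - cy, x - cx)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # wrap for periodic interpolation
  th_ext <- c(th - 2 * pi, th, th + 2 * pi)
  r_ext <- c(r, r, r)
  tq <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
  rq <- stats::approx(th_ext, r_ext, xout = tq, ties = mean)$y
  cbind(cx + rq * cos(tq), cy + rq * sin(tq))
}

## In-plane outward normals of a closed ring (perpendicular to the local
## tangent, oriented away from the ring centroid).
.ring_normals <- function(ring) {
  n <- nrow(ring)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  tx <- ring[nxt, 1] - ring[prv, 1]
  ty <- ring[nxt, 2] - ring[prv, 2]
  nx <- ty; ny <- -tx
  cx <- mean(ring[, 1]); cy <- mean(ring[, 2])
  flip <- (nx * (ring[, 1] - cx) + ny * (ring[, 2] - cy)) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  len <- sqrt(nx^2 + ny^2)
  cbind(nx / len, ny / len)
}

#' Restrict a mesh to a z band
#'
#' @param mesh a [cbt_mesh].
#' @param zmin,zmax band limits in mm (vertex z coordinate).
#' @return a [cbt_mesh] containing only vertices in the band (faces remapped).
#' @export
crop_mesh_z <- function(mesh, zmin, zmax) {
  keep <- which(mesh$vertices[, 3] >= zmin & mesh$vertices[, 3] <= zmax)
  if (length(keep) < 3L) stop("z band contains fewer than 3 vertices")
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  fok <- apply(matrix(mesh$faces %in% keep, ncol = 3), 1, all)
  faces <- matrix(remap[mesh$faces[fok, , drop = FALSE]], ncol = 3)
  cbt_mesh(mesh$vertices[keep, , drop = FALSE], faces,
           mesh$normals[keep, , drop = FALSE])
}

#' Sample a CT intensity profile along a surface normal
#'
#' Trilinear interpolation of the volume at offsets
#' `seq(-half_length, half_length, by = spacing)` along the line through
#' `point` in direction `-normal` (x = 0 at the surface point, positive x
#' inward — opposite the outward normal — so the soft-tissue level is always
#' on the negative side).
#'
#' @param volume a [ct_volume].
#' @param point surface point (mm, length 3).
#' @param normal outward unit normal at the point.
#' @param half_length half the profile length (mm).
#' @param spacing sample spacing (mm).
#' @return a [cbt_profile]; if part of the line leaves the volume the
#'   profile is truncated and flagged, and a fully outside line is an error.
#' @export
sample_profile <- function(volume, point, normal, half_length = 9,
                           spacing = 0.3) {
  if (spacing <= 0 || half_length <= 0)
    stop("half_length and spacing must be > 0")
  x <- seq(-half_length, half_length, by = spacing)
  if (length(x) < 8L)
    stop("spacing too coarse: fewer than 8 samples on the profile")
  nrm <- normal / sqrt(sum(normal^2))
  pts <- cbind(point[1] - x * nrm[1], point[2] - x * nrm[2],
               point[3] - x * nrm[3])
  v <- interp_trilinear(volume, pts)
  ok <- !is.na(v)
  if (!any(ok)) stop("profile line lies fully outside the volume")
  cbt_profile(x[ok], v[ok], truncated = !all(ok))
}

#' Estimate a per-vertex cortical thickness map
#'
#' The cortical-bone-mapping two-pass procedure over a whole mesh: at every
#' vertex an intensity profile is sampled along the inward normal and the
#' blurred two-edge model fitted with free cortical density; the global
#' cortical density is then estimated as the median over wide-cortex lines,
#' and every profile is refitted with the density fixed at that value (the
#' constant-density assumption). Per-vertex failures are recorded as
#' unconverged, never aborting the map.
#'
#' @param volume a [ct_volume].
#' @param mesh a [cbt_mesh] derived from (or registered to) the volume.
#' @param half_length,spacing profile geometry (mm); see [sample_profile()].
#' @param density_ratio identifiability threshold `t/sigma` for the global
#'   density pass.
#' @param bounds optional fit bounds, see [fit_profile()].
#' @return object of class `cbt_thickness_map`: `thickness` (mm, `NA` where
#'   unconverged), `converged`, `sigma`, `residual`, `global_density` (HU),
#'   `n_converged`.
#' @export
estimate_thickness_map <- function(volume, mesh, half_length = 9,
                                   spacing = 0.3, density_ratio = 3,
                                   bounds = list()) {
  nv <- nrow(mesh$vertices)
  profiles <- vector("list", nv)
  for (i in seq_len(nv)) {
    profiles[[i]] <- tryCatch(
      sample_profile(volume, mesh$vertices[i, ], mesh$normals[i, ],
                     half_length = half_length, spacing = spacing),
      error = function(e) NULL)
  }
  have <- !vapply(profiles, is.null, TRUE)
  fit_or_fail <- function(p, fixed) {
    tryCatch(fit_profile(p, fixed = fixed, bounds = bounds),
             error = function(e)
               structure(list(t = NA_real_, sigma = NA_real_, y1 = NA_real_,
                              residual = NA_real_, converged = FALSE),
                         class = "cbt_fit"))
  }
  pass1 <- lapply(profiles[have], fit_or_fail, fixed = list())
  dens <- estimate_global_density(pass1, ratio = density_ratio)
  pass2 <- lapply(profiles[have], fit_or_fail, fixed = list(y1 = dens))

  thickness <- rep(NA_real_, nv)
  converged <- rep(FALSE, nv)
  sig <- rep(NA_real_, nv)
  res <- rep(NA_real_, nv)
  idx <- which(have)
  for (j in seq_along(idx)) {
    f <- pass2[[j]]
    if (isTRUE(f$converged)) {
      thickness[idx[j]] <- f$t
      converged[idx[j]] <- TRUE
      sig[idx[j]] <- f$sigma
      res[idx[j]] <- f$residual
    }
  }
  structure(list(thickness = thickness, converged = converged, sigma = sig,
                 residual = res, global_density = dens,
                 n_converged = sum(converged)),
            class = "cbt_thickness_map")
}

#' @export
print.cbt_thickness_map <- function(x, ...) {
  cat("<cbt_thickness_map> ", length(x$thickness), " vertices, ",
      x$n_converged, " converged; global cortical density ",
      round(x$global_density), " HU\n", sep = "")
  invisible(x)
}

#' Smooth a thickness map over the surface
#'
#' Gaussian-weighted average over the mesh-neighbourhood of each vertex:
#' neighbours are vertices reachable through mesh edges within geodesic
#' (summed edge length) distance `radius`, weighted by
#' `exp(-d^2 / (2 * (radius/2)^2))`. Only converged vertices contribute;
#' `radius = 0` is the identity.
#'
#' @param map a `cbt_thickness_map`.
#' @param mesh the [cbt_mesh] the map lives on.
#' @param radius smoothing radius (mm), `>= 0`.
#' @return a smoothed `cbt_thickness_map`.
#' @export
filter_thickness_map <- function(map, mesh, radius) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(map)
  nv <- nrow(mesh$vertices)
  adj <- .mesh_adjacency(mesh)
  sd2 <- 2 * (radius / 2)^2
  out <- map$thickness
  for (i in which(map$converged)) {
    nb <- .geodesic_ball(i, adj, mesh$vertices, radius)
    ok <- nb$idx[map$converged[nb$idx]]
    d <- nb$dist[map$converged[nb$idx]]
    w <- exp(-d^2 / sd2)
    out[i] <- sum(w * map$thickness[ok]) / sum(w)
  }
  map$thickness <- out
  map
}

.mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- vector("list", max(f))
  sp <- split(e[, 2], e[, 1])
  adj[as.integer(names(sp))] <- lapply(sp, unique)
  adj
}

## Dijkstra-style ball: vertices within summed-edge-length `radius` of i.
.geodesic_ball <- function(i, adj, vertices, radius) {
  dist <- rep(Inf, nrow(vertices))
  dist[i] <- 0
  frontier <- i
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      nbs <- adj[[v]]
      if (is.null(nbs)) next
      dd <- dist[v] + sqrt(rowSums((vertices[nbs, , drop = FALSE] -
        matrix(vertices[v, ], nrow = length(nbs), ncol = 3, byrow = TRUE))^2))
      imp <- dd <= radius & dd < dist[nbs]
      if (any(imp)) {
        dist[nbs[imp]] <- dd[imp]
        nxt <- c(nxt, nbs[imp])
      }
    }
    frontier <- unique(nxt)
  }
  idx <- which(is.finite(dist))
  list(idx = idx, dist = dist[idx])
}
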