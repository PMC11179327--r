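# Anatomical axes, FTA and the medial-plateau coronal angle.

make_prism_mesh <- function(radius = 10, height = 100, bow = 0,
                            n_az = 24, n_z = 41) {
  th <- seq(0, 2 * pi, length.out = n_az + 1)[-(n_az + 1)]
  zs <- seq(0, height, length.out = n_z)
  verts <- do.call(rbind, lapply(zs, function(z) {
    # coronal bow: lateral offset peaking at mid-shaft
    dx <- bow * sin(pi * z / height)
    cbind(dx + radius * cos(th), radius * sin(th), z)
  }))
  normals <- do.call(rbind, lapply(zs, function(z)
    cbind(cos(th), sin(th), 0)))
  faces <- do.call(rbind, lapply(seq_len(n_z - 1), function(i) {
    a <- (i - 1) * n_az; b <- i * n_az
    do.call(rbind, lapply(seq_len(n_az), function(j) {
      j2 <- if (j == n_az) 1 else j + 1
      rbind(c(a + j, a + j2, b + j), c(a + j2, b + j2, b + j))
    }))
  }))
  cbt_mesh(verts, faces, normals)
}

identity_cs <- tibial_cs(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

test_that("centroid counts follow the bone type", {
  mesh <- make_prism_mesh()
  expect_equal(nrow(compute_section_centroids(mesh, identity_cs, "tibia")),
               12L)
  expect_equal(nrow(compute_section_centroids(mesh, identity_cs, "femur")),
               10L)
})

test_that("a straight prism has all centroids on its axis", {
  mesh <- make_prism_mesh()
  cent <- compute_section_centroids(mesh, identity_cs, "tibia")
  expect_lt(max(abs(cent[, 1:2])), 1e-6)
})

test_that("a bowed prism shows the constructed mid-shaft offset", {
  mesh <- make_prism_mesh(bow = 2, n_z = 201)
  cent <- compute_section_centroids(mesh, identity_cs, "tibia")
  mid <- cent[order(abs(cent[, 3] - 50))[1:2], ]
  expect_true(all(abs(mid[, 1] - 2 * sin(pi * mid[, 3] / 100)) < 0.05))
})

test_that("axis fitting is total least squares", {
  # collinear centroids: zero residual, exact direction
  t <- seq(0, 1, length.out = 12)
  line <- cbind(1 + 2 * t, -1 + 0.5 * t, 10 * t)
  ax <- fit_anatomical_axis(line)
  expect_lt(ax$rms_residual, 1e-9)
  expect_lt(angle_between(ax$direction, c(2, 0.5, 10)), 1e-9)
  expect_error(fit_anatomical_axis(line[1, , drop = FALSE]), "at least 2")
  expect_error(fit_anatomical_axis(matrix(1, 5, 3)), "coincide")
})

test_that("noisy axis fits match a direction-grid minimizer", {
  set.seed(17)
  t <- seq(0, 100, length.out = 12)
  pts <- cbind(0.05 * t, 0.02 * t, t) + matrix(rnorm(36, sd = 0.5), ncol = 3)
  ax <- fit_anatomical_axis(pts)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  obj <- function(ang) {
    d <- c(sin(ang[2]) * cos(ang[1]), sin(ang[2]) * sin(ang[1]),
           cos(ang[2]))
    sum(rowSums(X^2) - (X %*% d)^2)
  }
  oracle <- zoom_grid_search(obj, lower = c(-pi, 0), upper = c(pi, pi / 2),
                             n = 61L, levels = 7L)
  d_star <- c(sin(oracle$par[2]) * cos(oracle$par[1]),
              sin(oracle$par[2]) * sin(oracle$par[1]), cos(oracle$par[2]))
  expect_lt(angle_between(ax$direction, d_star), 1e-6)
})

test_that("FTA is anchored at 180 and signed toward varus", {
  fem <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  tib <- list(point = c(0, 0, 0), direction = c(0, 0, -1))
  expect_equal(compute_fta(fem, tib, identity_cs, "right")$fta, 180)
  # constructed 7-degree varus on a right limb
  a <- 7 * pi / 180
  fem7 <- list(point = c(0, 0, 0), direction = c(-sin(a), 0, cos(a)))
  f <- compute_fta(fem7, tib, identity_cs, "right")
  expect_equal(f$fta, 187, tolerance = 1e-9)
  expect_equal(f$varus_deviation, 7, tolerance = 1e-9)
  # 4.6-degree valgus lands on the healthy-female scale
  b <- -4.6 * pi / 180
  femv <- list(point = c(0, 0, 0), direction = c(-sin(b), 0, cos(b)))
  expect_equal(compute_fta(femv, tib, identity_cs, "right")$fta, 175.4,
               tolerance = 1e-9)
  # mirrored sign convention on the left
  expect_equal(compute_fta(fem7, tib, identity_cs, "left")$fta, 173,
               tolerance = 1e-9)
  expect_error(compute_fta(list(point = c(0, 0, 0),
                                direction = c(0, 1, 0)),
                           tib, identity_cs), "coronal")
})

test_that("FTA grows strictly with constructed varus", {
  tib <- list(point = c(0, 0, 0), direction = c(0, 0, -1))
  ftas <- vapply(c(-5, 0, 3, 7, 12), function(deg) {
    a <- deg * pi / 180
    fem <- list(point = c(0, 0, 0), direction = c(-sin(a), 0, cos(a)))
    compute_fta(fem, tib, identity_cs, "right")$fta
  }, 0)
  expect_true(all(diff(ftas) > 0))
})

test_that("plane fitting is exact on coplanar points and rejects lines", {
  pts <- generate_mct_points(0.2, 0.1, noise_sd = 0, seed = 3)
  pl <- fit_mct_plane(pts)
  expect_lt(pl$fit_rms, 1e-9)
  expect_lt(angle_between(pl$normal, c(-0.2, -0.1, 1)), 1e-9)
  expect_error(fit_mct_plane(pts[1:2, ]), "3 points")
  expect_error(fit_mct_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("noisy plane fits match a normal-grid minimizer", {
  set.seed(23)
  pts <- generate_mct_points(0.25, 0.05, noise_sd = 0.5, n = 30, seed = 24)
  pl <- fit_mct_plane(pts)
  X <- sweep(pts, 2, colMeans(pts))
  obj <- function(ang) {
    nrm <- c(sin(ang[2]) * cos(ang[1]), sin(ang[2]) * sin(ang[1]),
             cos(ang[2]))
    sum((X %*% nrm)^2)
  }
  oracle <- zoom_grid_search(obj, lower = c(-pi, 0), upper = c(pi, pi / 2),
                             n = 61L, levels = 7L)
  n_star <- c(sin(oracle$par[2]) * cos(oracle$par[1]),
              sin(oracle$par[2]) * sin(oracle$par[1]), cos(oracle$par[2]))
  expect_lt(angle_between(pl$normal, n_star), 1e-6)
})

test_that("the MCT coronal angle isolates the coronal slope", {
  horiz <- fit_mct_plane(generate_mct_points(0, 0, seed = 5))
  expect_equal(mct_coronal_angle(horiz, identity_cs), 0)
  b <- tan(12.2 * pi / 180)
  tilted <- fit_mct_plane(generate_mct_points(b, 0, seed = 6))
  expect_equal(mct_coronal_angle(tilted, identity_cs), 12.2,
               tolerance = 1e-9)
  # adding sagittal tilt changes nothing
  both <- fit_mct_plane(generate_mct_points(b, 0.3, seed = 7))
  expect_equal(mct_coronal_angle(both, identity_cs), 12.2,
               tolerance = 1e-9)
  # a plane parallel to the coronal plane has no crossing line
  vert <- list(normal = c(0, 1, 0), offset = 0)
  expect_error(mct_coronal_angle(vert, identity_cs), "parallel")
})

test_that("FTA and MCT angle are invariant under rigid motion", {
  R <- rotation_matrix(c(2, -1, 0.5), 0.8)
  shift <- c(5, 6, -7)
  a <- 7 * pi / 180
  fem <- list(point = c(0, 0, 0), direction = c(-sin(a), 0, cos(a)))
  tib <- list(point = c(0, 0, 0), direction = c(0, 0, -1))
  cs_r <- tibial_cs(shift, R[, 1], R[, 2], R[, 3])
  fem_r <- list(point = as.numeric(R %*% fem$point) + shift,
                direction = as.numeric(R %*% fem$direction))
  tib_r <- list(point = shift, direction = as.numeric(R %*% tib$direction))
  expect_equal(compute_fta(fem_r, tib_r, cs_r, "right")$fta, 187,
               tolerance = 1e-6)
  b <- tan(9 * pi / 180)
  pts <- generate_mct_points(b, 0.1, seed = 9)
  pl0 <- fit_mct_plane(pts)
  pts_r <- t(R %*% t(pts)) + matrix(shift, nrow(pts), 3, byrow = TRUE)
  pl1 <- fit_mct_plane(pts_r)
  expect_equal(mct_coronal_angle(pl1, cs_r),
               mct_coronal_angle(pl0, identity_cs), tolerance = 1e-6)
})
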