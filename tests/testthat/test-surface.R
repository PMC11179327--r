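# Surface extraction, profile sampling and the thickness map.

make_cylinder_volume <- function(radius = 10, height = 30, sigma = 0.9,
                                 noise_sd = 0, seed = 2) {
  spec <- phantom_spec(tibial_length = height,
                       outer_radius = function(h) rep(radius, length(h)),
                       thickness_field = function(h, theta)
                         rep(5, length(h)),
                       noise_sd = noise_sd, seed = seed)
  generate_tibia_phantom(spec)$volume
}

test_that("trilinear interpolation is exact on a linear field", {
  ax <- list(0:10, 0:8, 0:6)
  arr <- array(0, dim = c(11, 9, 7))
  for (i in 1:11) for (j in 1:9) for (k in 1:7)
    arr[i, j, k] <- 2 * (i - 1) - 3 * (j - 1) + 0.5 * (k - 1) + 7
  vol <- ct_volume(arr)
  set.seed(4)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 8), runif(50, 0, 6))
  expect_equal(interp_trilinear(vol, pts),
               2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3] + 7,
               tolerance = 1e-12)
  expect_true(is.na(interp_trilinear(vol, cbind(-1, 0, 0))))
})

test_that("iso-surface vertices sit on the cylinder at sub-voxel accuracy", {
  vol <- make_cylinder_volume(radius = 10, height = 30)
  mesh <- extract_surface(vol, threshold = 600, slice_step = 2,
                          n_azimuth = 36, z_range = c(5, 25))
  r <- sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2)
  expect_lt(abs(mean(r) - 10), 0.35)
  expect_lt(max(abs(r - 10)), 0.35)   # half the in-plane voxel size
})

test_that("surface normals point outward and have unit length", {
  vol <- make_cylinder_volume()
  mesh <- extract_surface(vol, threshold = 600, z_range = c(5, 25))
  expect_lt(max(abs(sqrt(rowSums(mesh$normals^2)) - 1)), 1e-6)
  radial <- cbind(mesh$vertices[, 1], mesh$vertices[, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_true(all(rowSums(mesh$normals * radial) > 0))
})

test_that("an all-background volume is an empty segmentation", {
  vol <- ct_volume(array(0, dim = c(10, 10, 10)))
  expect_error(extract_surface(vol, threshold = 600), "empty segmentation")
})

test_that("profiles sampled from the phantom match the generating closed form", {
  # fine in-plane voxels: the residual is pure trilinear-interpolation error,
  # which shrinks quadratically with voxel size
  spec <- phantom_spec(tibial_length = 30,
                       outer_radius = function(h) rep(10, length(h)),
                       thickness_field = function(h, theta) rep(5, length(h)),
                       voxel_spacing = c(0.35, 0.35, 1), noise_sd = 0)
  vol <- generate_tibia_phantom(spec)$volume
  # radial line through a surface point at mid-height
  p <- sample_profile(vol, point = c(10, 0, 15), normal = c(1, 0, 0),
                      half_length = 8, spacing = 0.3)
  expected <- cbt_profile_model(p$x, 0, 1200, 300, x0 = 0, t = 5,
                                sigma = 0.9)
  expect_lt(sqrt(mean((p$value - expected)^2)), 2)
  # constant volume gives a constant profile
  volc <- ct_volume(array(55, dim = c(30, 30, 30)))
  pc <- sample_profile(volc, c(15, 15, 15), c(1, 0, 0), half_length = 4,
                       spacing = 0.5)
  expect_true(all(abs(pc$value - 55) < 1e-12))
})

test_that("degenerate profile sampling is rejected", {
  vol <- make_cylinder_volume()
  expect_error(sample_profile(vol, c(10, 0, 15), c(1, 0, 0),
                              half_length = 2, spacing = 3), "8 samples")
  expect_error(sample_profile(vol, c(500, 0, 0), c(1, 0, 0)),
               "outside the volume")
})

test_that("the two-pass map recovers uniform thickness and is deterministic", {
  spec <- small_phantom_spec(thickness = 5, noise_sd = 20, L = 60)
  ph <- generate_tibia_phantom(spec)
  mesh <- extract_surface(ph$volume, slice_step = 6, n_azimuth = 16,
                          z_range = c(10, 50))
  map1 <- estimate_thickness_map(ph$volume, mesh)
  expect_gte(map1$n_converged / nrow(mesh$vertices), 0.95)
  expect_lt(abs(mean(map1$thickness, na.rm = TRUE) - 5), 0.1)
  map2 <- estimate_thickness_map(ph$volume, mesh)
  expect_identical(map1, map2)
})

test_that("surface filtering preserves constants, range, and the identity", {
  spec <- split_phantom_spec(L = 60)
  ph <- generate_tibia_phantom(spec)
  mesh <- extract_surface(ph$volume, slice_step = 10, n_azimuth = 16,
                          z_range = c(15, 45))
  map <- estimate_thickness_map(ph$volume, mesh)
  expect_identical(filter_thickness_map(map, mesh, 0), map)
  sm <- filter_thickness_map(map, mesh, 6)
  rng <- range(map$thickness, na.rm = TRUE)
  expect_true(all(sm$thickness >= rng[1] - 1e-12, na.rm = TRUE))
  expect_true(all(sm$thickness <= rng[2] + 1e-12, na.rm = TRUE))
  # constant map is unchanged
  mapc <- map
  mapc$thickness[mapc$converged] <- 3
  smc <- filter_thickness_map(mapc, mesh, 6)
  expect_true(all(abs(smc$thickness[smc$converged] - 3) < 1e-12))
  expect_error(filter_thickness_map(map, mesh, -1), "radius")
})
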