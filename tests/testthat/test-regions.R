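# Height bands, sectors, standardization and the 24-region aggregation.

test_that("tibial length is the distance between the two midpoints", {
  lm <- list(eminence_medial = c(-8, 0, 330), eminence_lateral = c(8, 0, 330),
             talar_dome_medial = c(-9, 0, 0), talar_dome_lateral = c(9, 0, 0))
  expect_equal(compute_tibial_length(lm), 330)
  # symmetric perturbation of the eminence pair leaves L unchanged
  lm2 <- lm
  lm2$eminence_medial <- lm$eminence_medial + c(3, 2, -1)
  lm2$eminence_lateral <- lm$eminence_lateral - c(3, 2, -1)
  expect_equal(compute_tibial_length(lm2), 330)
  lm3 <- lm
  lm3$eminence_medial <- c(-9, 0, 0); lm3$eminence_lateral <- c(9, 0, 0)
  expect_error(compute_tibial_length(lm3), "coincide")
})

test_that("height bands follow the documented half-open convention", {
  expect_equal(assign_height_band(0.65), "most proximal")
  expect_equal(assign_height_band(0.25), "outside")
  expect_equal(assign_height_band(0.75), "outside")
  # boundary fractions go to the band whose lower edge they are
  expect_equal(assign_height_band(0.50), "central proximal")
  expect_equal(assign_height_band(0.37), "distal")
  expect_equal(assign_height_band(0.30), "most distal")
  # uppermost band is closed
  expect_equal(assign_height_band(0.70), "most proximal")
  expect_equal(assign_height_band(c(0.35, 0.45, 0.60)),
               c("most distal", "central distal", "proximal"))
})

test_that("sectors are 90-degree wedges with mirroring by side", {
  # right tibia: medial is -x
  expect_equal(assign_sector(-1, 0, "right"), "medial")
  expect_equal(assign_sector(1, 0, "right"), "lateral")
  expect_equal(assign_sector(0, 1, "right"), "anterior")
  expect_equal(assign_sector(0, -1, "right"), "posterior")
  # left tibia mirrors
  expect_equal(assign_sector(1, 0, "left"), "medial")
  expect_equal(assign_sector(-1, 0, "left"), "lateral")
  # exact 45-degree boundary between medial and anterior -> anterior
  expect_equal(assign_sector(-1, 1, "right"), "anterior")
  expect_error(assign_sector(0, 0, "right"), "z-axis")
})

test_that("standardization is actual/L on the 10^-3 scale", {
  expect_equal(standardize_cbt(5, 250), 20)
  expect_equal(standardize_cbt(0, 250), 0)
  expect_equal(standardize_cbt(10, 500), standardize_cbt(5, 250))
  expect_error(standardize_cbt(5, 0), "L must be > 0")
})

test_that("all 24 regions exist and every diaphyseal vertex has exactly one", {
  labels <- region_labels()
  expect_equal(nrow(labels), 24L)
  expect_equal(nrow(unique(labels)), 24L)
  expect_setequal(unique(labels$band),
                  c("most proximal", "proximal", "central proximal",
                    "central distal", "distal", "most distal"))
  expect_setequal(unique(labels$sector),
                  c("medial", "anterior", "lateral", "posterior"))
  # exhaustive partition over a dense grid of diaphyseal positions
  set.seed(13)
  zf <- runif(5000, 0.30, 0.70)
  band <- assign_height_band(zf)
  expect_true(all(band != "outside"))
  th <- runif(5000, -pi, pi)
  sector <- assign_sector(cos(th), sin(th), "right")
  expect_true(all(sector %in% labels$sector))
  hits <- table(paste(band, sector))
  expect_true(all(paste(labels$band, labels$sector) %in% names(hits)))
})

test_that("a uniform phantom aggregates to its known thickness", {
  res <- run_phantom_study(small_phantom_spec(thickness = 5, L = 250,
                                              noise_sd = 20),
                           slice_step = 6, n_azimuth = 16)
  reg <- res$regions
  expect_equal(nrow(reg$regional), 24L)
  expect_equal(reg$tibial_length, 250)
  expect_true(all(abs(reg$regional$mean_actual - 5) < 0.1))
  expect_true(all(abs(reg$regional$mean_standardized - 20) < 0.4))
  expect_true(all(abs(reg$ratios$ml_ratio - 1) < 0.05))
  expect_true(all(abs(reg$ratios$ap_ratio - 1) < 0.05))
  expect_lt(max(abs(reg$regional$mean_standardized -
                      reg$regional$mean_actual / reg$tibial_length * 1e3)),
            1e-9)
})

test_that("a medial/lateral split phantom yields the constructed M/L ratio", {
  res <- run_phantom_study(split_phantom_spec(t_medial = 6, t_lateral = 4,
                                              L = 250),
                           slice_step = 6, n_azimuth = 16)
  reg <- res$regions
  mp <- reg$regional[reg$regional$band == "most proximal", ]
  expect_lt(abs(mp$mean_actual[mp$sector == "medial"] - 6), 0.3)
  expect_lt(abs(mp$mean_actual[mp$sector == "lateral"] - 4), 0.3)
  ml <- reg$ratios$ml_ratio[reg$ratios$band == "most proximal"]
  expect_lt(abs(ml - 1.5), 0.1)
})

test_that("aggregation is invariant to vertex order", {
  res <- run_phantom_study(small_phantom_spec(thickness = 4, L = 250,
                                              seed = 21),
                           slice_step = 10, n_azimuth = 12)
  perm <- sample(nrow(res$mesh$vertices))
  mesh_p <- cbt_mesh(res$mesh$vertices[perm, ],
                     matrix(match(res$mesh$faces, perm), ncol = 3),
                     res$mesh$normals[perm, ])
  map_p <- res$map
  map_p$thickness <- res$map$thickness[perm]
  map_p$converged <- res$map$converged[perm]
  reg_p <- aggregate_regions(map_p, mesh_p, res$cs, res$truth$landmarks,
                             side = "right")
  expect_equal(reg_p$regional$mean_actual, res$regions$regional$mean_actual,
               tolerance = 1e-12)
  expect_equal(reg_p$regional$n_points, res$regions$regional$n_points)
})
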