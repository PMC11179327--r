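#' Run the full phantom morphometry pipeline
#'
#' End-to-end driver over a synthetic tibia: generate the phantom volume,
#' extract the periosteal surface, estimate the two-pass cortical thickness
#' map over the diaphysis, build the anatomical tibial frame, aggregate the
#' 24 standard regions, and compute the FTA (against the phantom's femoral
#' axis) and the MCT coronal angle (from digitized plateau points). Every
#' stage runs off the previous one, so this is also the integration test of
#' the whole package.
#'
#' @param spec a [phantom_spec].
#' @param slice_step,n_azimuth surface-extraction density (see
#'   [extract_surface()]); the defaults give roughly 800 diaphyseal
#'   measurement sites.
#' @param half_length,spacing profile geometry in mm.
#' @param filter_radius optional surface smoothing radius (mm); 0 disables.
#' @param mct_noise_sd digitization noise of the plateau points (mm).
#' @param out_dir optional directory; when given, writes the thickness PLY,
#'   regional/ratio CSVs, morphometry CSV, landmark and frame JSON.
#' @return list with `volume`, `truth`, `mesh` (diaphyseal), `map`,
#'   `cs`, `regions`, `fta`, `mct_angle`, `tibial_axis`.
#' @export
run_phantom_study <- function(spec = phantom_spec(),
                              slice_step = 4L, n_azimuth = 24L,
                              half_length = 9, spacing = 0.3,
                              filter_radius = 0,
                              mct_noise_sd = 0,
                              out_dir = NULL) {
  ph <- generate_tibia_phantom(spec)
  L <- spec$tibial_length

  # full-length mesh for frame construction, diaphyseal band for mapping
  mesh_full <- extract_surface(ph$volume, slice_step = slice_step,
                               n_azimuth = n_azimuth)
  mesh_dia <- crop_mesh_z(mesh_full, 0.28 * L, 0.72 * L)

  map <- estimate_thickness_map(ph$volume, mesh_dia,
                                half_length = half_length,
                                spacing = spacing)
  if (filter_radius > 0)
    map <- filter_thickness_map(map, mesh_dia, filter_radius)

  cs <- build_tibial_cs(mesh_full, ph$truth$landmarks)
  regions <- aggregate_regions(map, mesh_dia, cs, ph$truth$landmarks,
                               side = spec$side)

  centroids_cs <- compute_section_centroids(mesh_full, cs, bone = "tibia")
  tibial_axis_cs <- fit_anatomical_axis(centroids_cs)
  # back to world coordinates for the FTA
  tibial_axis <- list(
    point = from_cs(tibial_axis_cs$point, cs),
    direction = as.numeric(cbind(cs$x_axis, cs$y_axis, cs$z_axis) %*%
                             tibial_axis_cs$direction),
    rms_residual = tibial_axis_cs$rms_residual,
    n_centroids = tibial_axis_cs$n_centroids)

  fta <- compute_fta(ph$truth$femoral_axis, tibial_axis,
                     ph$truth$femoral_cs, side = spec$side)

  mct_pts_cs <- generate_mct_points(spec$mct_coronal_slope,
                                    sagittal_slope = 0.05,
                                    noise_sd = mct_noise_sd,
                                    seed = spec$seed + 1L,
                                    side = spec$side)
  mct_plane <- fit_mct_plane(from_cs(mct_pts_cs, cs))
  mct_angle <- mct_coronal_angle(mct_plane, cs)

  out <- list(volume = ph$volume, truth = ph$truth, mesh = mesh_dia,
              map = map, cs = cs, regions = regions,
              tibial_axis = tibial_axis, fta = fta,
              mct_plane = mct_plane, mct_angle = mct_angle)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ply(mesh_dia, file.path(out_dir, "thickness_map.ply"),
              vertex_props = list(
                thickness = ifelse(is.na(map$thickness), -1, map$thickness),
                quality = as.numeric(map$converged)))
    write_regional_csv(regions,
                       file.path(out_dir, "regional_cbt.csv"),
                       file.path(out_dir, "regional_ratios.csv"))
    utils::write.csv(
      data.frame(fta_deg = fta$fta, varus_deviation_deg = fta$varus_deviation,
                 mct_coronal_angle_deg = mct_angle,
                 tibial_axis_rms_mm = tibial_axis$rms_residual,
                 global_density_hu = map$global_density,
                 n_converged = map$n_converged),
      file.path(out_dir, "morphometry.csv"), row.names = FALSE)
    write_landmarks_json(ph$truth$landmarks,
                         file.path(out_dir, "landmarks.json"))
    write_frame_json(cs, file.path(out_dir, "tibial_frame.json"))
  }
  out
}
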