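# Shared fixtures: small, fast phantoms and geometric helpers.

# A short uniform-thickness tibia phantom for integration-style unit tests.
small_phantom_spec <- function(thickness = 5, noise_sd = 0, L = 250,
                               seed = 11L, ...) {
  phantom_spec(
    tibial_length = L,
    outer_radius = function(h) rep(12, length(h)),
    thickness_field = function(h, theta) rep(thickness, length(h)),
    noise_sd = noise_sd, seed = seed, ...)
}

# Medial/lateral split thickness: medial (= -x on a right tibia) thick.
split_phantom_spec <- function(t_medial = 6, t_lateral = 4, L = 250,
                               seed = 12L, ...) {
  phantom_spec(
    tibial_length = L,
    outer_radius = function(h) rep(12, length(h)),
    thickness_field = function(h, theta) {
      mid <- (t_medial + t_lateral) / 2
      amp <- (t_medial - t_lateral) / 2
      mid - amp * cos(theta)   # -x (medial, right side) gets t_medial
    },
    noise_sd = 0, seed = seed, ...)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotate_landmarks <- function(landmarks, R, shift = c(0, 0, 0)) {
  out <- lapply(landmarks, function(p) {
    if (is.numeric(p) && length(p) == 3) as.numeric(R %*% p) + shift
    else list(vertices = t(R %*% t(p$vertices)) +
                matrix(shift, nrow(p$vertices), 3, byrow = TRUE),
              faces = p$faces)
  })
  out
}

rotate_mesh <- function(mesh, R, shift = c(0, 0, 0)) {
  cbt_mesh(t(R %*% t(mesh$vertices)) +
             matrix(shift, nrow(mesh$vertices), 3, byrow = TRUE),
           mesh$faces,
           t(R %*% t(mesh$normals)))
}

angle_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(abs(sum(a * b)), 1))   # line angle, orientation-free
}

# Hierarchical (zoomed) grid search over a 1D or 2D objective; a pure grid
# refinement, independent of any analytic fit it is used to check.
zoom_grid_search <- function(f, lower, upper, n = 21L, levels = 6L) {
  lo <- lower; hi <- upper
  best <- NULL
  for (lv in seq_len(levels)) {
    grids <- Map(function(a, b) seq(a, b, length.out = n), lo, hi)
    pts <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(pts, 1, f)
    i <- which.min(vals)
    best <- pts[i, ]
    step <- (hi - lo) / (n - 1)
    lo <- pmax(lower, best - step)
    hi <- pmin(upper, best + step)
  }
  list(par = best, value = min(vals))
}

# The default full-pipeline run is shared by several acceptance checks;
# computed once per test session.
.pipeline_cache <- new.env()
default_phantom_run <- function() {
  if (is.null(.pipeline_cache$res))
    .pipeline_cache$res <- run_phantom_study(phantom_spec())
  .pipeline_cache$res
}
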