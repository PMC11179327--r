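#' Blurred two-edge cortical intensity model
#'
#' Closed-form CT intensity along a line crossing the cortex: a three-level
#' density step (soft tissue `y0`, cortical `y1`, trabecular `y2`) with edges
#' at `x0` (periosteal) and `x0 + t` (endosteal), blurred by a Gaussian
#' point-spread function of width `sigma`. Offsets `x` are in mm along the
#' line, oriented positive inward, so `y0` is always the outside level:
#'
#' `y(x) = y0 + (y1 - y0) * pnorm((x - x0)/sigma) + (y2 - y1) * pnorm((x - x0 - t)/sigma)`
#'
#' @param x numeric vector of offsets along the line (mm; positive inward).
#' @param y0,y1,y2 soft-tissue, cortical and trabecular levels (HU).
#' @param x0 position of the outer (periosteal) edge (mm).
#' @param t cortical thickness (mm); inner edge lies at `x0 + t`.
#' @param sigma Gaussian blur width (mm), `> 0`.
#' @return numeric vector of model intensities (HU) at `x`.
#' @export
cbt_profile_model <- function(x, y0, y1, y2, x0, t, sigma) {
  stopifnot(sigma > 0, t > 0)
  y0 + (y1 - y0) * stats::pnorm((x - x0) / sigma) +
    (y2 - y1) * stats::pnorm((x - x0 - t) / sigma)
}

#' Construct a profile-samples object
#'
#' @param x strictly increasing offsets (mm, positive inward).
#' @param value HU values at each offset.
#' @param truncated flag set when a sampled line left the volume.
#' @return object of class `cbt_profile` with fields `x`, `value`, `truncated`.
#' @export
cbt_profile <- function(x, value, truncated = FALSE) {
  if (length(x) != length(value)) stop("x and value must have equal length")
  if (length(x) < 8L) stop("a profile needs at least 8 samples")
  if (any(diff(x) <= 0)) stop("profile offsets x must be strictly increasing")
  structure(list(x = as.numeric(x), value = as.numeric(value),
                 truncated = isTRUE(truncated)),
            class = "cbt_profile")
}

#' Generate a synthetic blurred line profile
#'
#' Samples the closed-form blurred two-edge model on a regular grid of
#' offsets `seq(-half_length, half_length, by = spacing)` and adds i.i.d.
#' Gaussian noise. Used both as the phantom's measurement model and as the
#' benchmark generator for the thickness estimator.
#'
#' @param t true cortical thickness (mm), `> 0`.
#' @param x0 outer-edge position (mm) relative to the nominal surface point.
#' @param densities numeric vector `c(y0, y1, y2)` (HU); cortex must be the
#'   densest (`y1 > y2 > y0`).
#' @param sigma blur width (mm), `> 0`.
#' @param spacing sample spacing (mm), `> 0`.
#' @param half_length half the profile length (mm); must contain both edges,
#'   `half_length >= x0 + t + 3 * sigma`.
#' @param noise_sd additive Gaussian noise SD (HU), `>= 0`.
#' @param seed optional integer seed for the noise.
#' @return a [cbt_profile].
#' @export
generate_line_profile <- function(t, x0 = 0, densities = c(0, 1200, 300),
                                  sigma = 0.9, spacing = 0.3,
                                  half_length = 9, noise_sd = 0,
                                  seed = NULL) {
  if (!is.numeric(t) || t <= 0) stop("thickness t must be > 0")
  if (spacing <= 0) stop("spacing must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(densities) != 3L) stop("densities must be c(y0, y1, y2)")
  if (half_length < x0 + t + 3 * sigma)
    stop("half_length too short to contain both cortical edges (need >= x0 + t + 3*sigma)")
  x <- seq(-half_length, half_length, by = spacing)
  y <- cbt_profile_model(x, densities[1], densities[2], densities[3],
                         x0 = x0, t = t, sigma = sigma)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  cbt_profile(x, y)
}

## Linear (density) sub-problem of the model fit: given the nonlinear
## parameters the model is linear in (y0, y1, y2) through the basis
## [1-P1, P1-P2, P2]. Fixed densities move to the offset side.
.cbt_density_solve <- function(x, y, x0, t, sigma, fixed) {
  p1 <- stats::pnorm((x - x0) / sigma)
  p2 <- stats::pnorm((x - x0 - t) / sigma)
  basis <- cbind(y0 = 1 - p1, y1 = p1 - p2, y2 = p2)
  free <- setdiff(colnames(basis), names(fixed))
  rhs <- y
  for (nm in intersect(colnames(basis), names(fixed)))
    rhs <- rhs - basis[, nm] * fixed[[nm]]
  dens <- c(y0 = NA_real_, y1 = NA_real_, y2 = NA_real_)
  for (nm in names(fixed)) if (nm %in% names(dens)) dens[nm] <- fixed[[nm]]
  if (length(free) > 0L) {
    fit <- stats::.lm.fit(basis[, free, drop = FALSE], rhs)
    dens[free] <- fit$coefficients
    res <- fit$residuals
  } else {
    res <- rhs
  }
  list(densities = dens, residuals = res, rss = sum(res^2))
}

## Gradient-based initialisation of the two edge positions from the
## lightly smoothed profile: the periosteal edge is the strongest rise,
## the endosteal edge the strongest fall further in.
.cbt_init_edges <- function(x, y) {
  k <- min(5L, length(y))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  g <- diff(ys) / diff(x)
  xm <- (x[-1] + x[-length(x)]) / 2
  i_up <- which.max(g)
  x0 <- xm[i_up]
  after <- which(xm > x0 + 0.25)
  x1 <- if (length(after) > 0L) xm[after[which.min(g[after])]] else x0 + 2
  c(x0 = x0, t = max(x1 - x0, 0.5))
}

#' Fit the blurred two-edge model to an intensity profile
#'
#' Bounded nonlinear least squares for the cortical model parameters. The
#' three density levels enter the model linearly, so the optimisation runs
#' over the nonlinear parameters (`x0`, `t`, `sigma`) only, with the free
#' densities solved by linear least squares at every step (variable
#' projection). Any of `y0`, `y1`, `y2`, `sigma`, `x0` may be held fixed;
#' fixing `y1` is the constant-cortical-density mode used in the second pass
#' of the thickness mapping.
#'
#' @param profile a [cbt_profile].
#' @param fixed named list of parameters to hold constant, e.g.
#'   `list(y1 = 1150)`; recognised names: `y0`, `y1`, `y2`, `sigma`, `x0`.
#' @param bounds named list of `c(lower, upper)` for `t`, `sigma`, `x0`.
#'   Defaults: `t` in \[0.3, 15\] mm, `sigma` in \[0.2, 3\] mm, `x0` within
#'   the sampled range.
#' @param starts optional matrix of extra starting points (columns `x0`,
#'   `t`, `sigma`) tried in addition to the gradient-based initialisation.
#' @return list of class `cbt_fit`: `y0`, `y1`, `y2` (HU), `x0`, `x1`, `t`,
#'   `sigma` (mm), `residual` (HU RMS), `converged`.
#' @export
fit_profile <- function(profile, fixed = list(), bounds = list(), starts = NULL) {
  if (!inherits(profile, "cbt_profile")) profile <- do.call(cbt_profile, profile)
  x <- profile$x
  y <- profile$value
  b <- list(t = c(0.3, 15), sigma = c(0.2, 3),
            x0 = c(min(x) + 0.3, max(x) - 0.3))
  b[names(bounds)] <- bounds
  fix_sigma <- "sigma" %in% names(fixed)
  fix_x0 <- "x0" %in% names(fixed)
  dens_fixed <- fixed[intersect(names(fixed), c("y0", "y1", "y2"))]

  par_names <- c(if (!fix_x0) "x0", "t", if (!fix_sigma) "sigma")
  lower <- vapply(par_names, function(p) b[[p]][1], 0)
  upper <- vapply(par_names, function(p) b[[p]][2], 0)

  resid_fun <- function(par) {
    names(par) <- par_names
    x0 <- if (fix_x0) fixed$x0 else par[["x0"]]
    sg <- if (fix_sigma) fixed$sigma else par[["sigma"]]
    .cbt_density_solve(x, y, x0, par[["t"]], sg, dens_fixed)$residuals
  }

  init <- .cbt_init_edges(x, y)
  start_list <- list(c(x0 = unname(init["x0"]), t = unname(init["t"]), sigma = 1))
  for (t0 in c(1, 4)) {
    start_list[[length(start_list) + 1L]] <-
      c(x0 = unname(init["x0"]), t = t0, sigma = 1)
  }
  if (!is.null(starts)) {
    for (i in seq_len(nrow(starts))) {
      start_list[[length(start_list) + 1L]] <-
        c(x0 = starts[i, "x0"], t = starts[i, "t"], sigma = starts[i, "sigma"])
    }
  }

  best <- NULL
  for (s in start_list) {
    p0 <- pmin(pmax(s[par_names], lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 80, ptol = 1e-10, ftol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$deviance < best$deviance)) {
      best <- res
    }
  }
  if (is.null(best)) stop("profile fit failed from every starting point")

  par <- best$par
  names(par) <- par_names
  x0_hat <- if (fix_x0) fixed$x0 else par[["x0"]]
  sg_hat <- if (fix_sigma) fixed$sigma else par[["sigma"]]
  t_hat <- par[["t"]]
  sol <- .cbt_density_solve(x, y, x0_hat, t_hat, sg_hat, dens_fixed)
  at_bound <- abs(t_hat - b$t[1]) < 1e-8 || abs(t_hat - b$t[2]) < 1e-8 ||
    (!fix_sigma && (abs(sg_hat - b$sigma[1]) < 1e-8 ||
                      abs(sg_hat - b$sigma[2]) < 1e-8))
  structure(list(
    y0 = unname(sol$densities["y0"]), y1 = unname(sol$densities["y1"]),
    y2 = unname(sol$densities["y2"]),
    x0 = unname(x0_hat), x1 = unname(x0_hat + t_hat), t = unname(t_hat),
    sigma = unname(sg_hat),
    residual = sqrt(sol$rss / length(x)),
    converged = best$info %in% 1:4 && !at_bound && is.finite(sol$rss)
  ), class = "cbt_fit")
}

#' Estimate the global cortical density from a set of profile fits
#'
#' Robust central estimate (median) of the per-line cortical level `y1` over
#' the high-confidence subset: converged fits whose thickness is wide enough
#' relative to the blur (`t >= ratio * sigma`) for `y1` to be identifiable.
#'
#' @param fits list of `cbt_fit` objects from a free-`y1` pass.
#' @param ratio identifiability threshold on `t / sigma` (default 3).
#' @return scalar cortical density estimate (HU).
#' @export
estimate_global_density <- function(fits, ratio = 3) {
  ok <- vapply(fits, function(f)
    isTRUE(f$converged) && is.finite(f$y1) && f$t >= ratio * f$sigma, TRUE)
  if (!any(ok))
    stop("no converged fit with t >= ", ratio,
         "*sigma; relax the identifiability threshold `ratio`")
  stats::median(vapply(fits[ok], function(f) f$y1, 0))
}

#' Two-pass thickness estimation on a set of profiles
#'
#' The cortical-bone-mapping fit schedule: a first pass with free cortical
#' density, a robust global density estimate over wide-cortex lines, then a
#' second pass with the density held at that global value (the
#' constant-density assumption that gives the method its sub-voxel accuracy
#' on thin cortices).
#'
#' @param profiles list of [cbt_profile] objects.
#' @param fixed_other optional named list of additional parameters held fixed
#'   in both passes (e.g. `list(y0 = 0)`).
#' @param density_ratio passed to [estimate_global_density()].
#' @return list with `fits` (second-pass `cbt_fit`s), `global_density` (HU),
#'   and `first_pass` fits.
#' @export
fit_profiles_two_pass <- function(profiles, fixed_other = list(),
                                  density_ratio = 3) {
  pass1 <- lapply(profiles, function(p)
    tryCatch(fit_profile(p, fixed = fixed_other), error = function(e) {
      structure(list(converged = FALSE, t = NA_real_, sigma = NA_real_,
                     y1 = NA_real_), class = "cbt_fit")
    }))
  dens <- estimate_global_density(pass1, ratio = density_ratio)
  fixed2 <- c(list(y1 = dens), fixed_other)
  pass2 <- lapply(profiles, function(p)
    tryCatch(fit_profile(p, fixed = fixed2), error = function(e) {
      structure(list(converged = FALSE, t = NA_real_, sigma = NA_real_,
                     y1 = dens), class = "cbt_fit")
    }))
  list(fits = pass2, global_density = dens, first_pass = pass1)
}
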