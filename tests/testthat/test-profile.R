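# Blurred two-edge profile model: generation and model-based fitting.

test_that("noiseless generated profiles equal the blurred closed form", {
  for (par in list(c(t = 2, sigma = 1.0), c(t = 5, sigma = 0.7),
                   c(t = 8, sigma = 1.3))) {
    p <- generate_line_profile(par[["t"]], x0 = 0.4, sigma = par[["sigma"]],
                               spacing = 0.3, half_length = 14)
    expected <- cbt_profile_model(p$x, 0, 1200, 300, x0 = 0.4,
                                  t = par[["t"]], sigma = par[["sigma"]])
    expect_lt(max(abs(p$value - expected)), 1e-9)
  }
})

test_that("degenerate blur gives a piecewise-constant three-level profile", {
  p <- generate_line_profile(5, x0 = 0, sigma = 1e-4, spacing = 0.5,
                             half_length = 9)
  expect_true(all(abs(p$value[p$x < -0.1] - 0) < 1e-9))
  expect_true(all(abs(p$value[p$x > 0.1 & p$x < 4.9] - 1200) < 1e-9))
  expect_true(all(abs(p$value[p$x > 5.1] - 300) < 1e-9))
})

test_that("profile generation is reproducible and validates its inputs", {
  p1 <- generate_line_profile(3, sigma = 1, noise_sd = 25, seed = 5)
  p2 <- generate_line_profile(3, sigma = 1, noise_sd = 25, seed = 5)
  expect_identical(p1, p2)
  expect_error(generate_line_profile(-1), "thickness")
  expect_error(generate_line_profile(5, x0 = 0, sigma = 1, half_length = 6),
               "half_length")
})

test_that("noisy profile means converge to the closed form", {
  # Monte-Carlo mean at every sample within 3 standard errors
  reps <- 1e4
  set.seed(101)
  acc <- 0
  for (i in seq_len(reps)) {
    p <- generate_line_profile(2, sigma = 1, spacing = 0.7, half_length = 9,
                               noise_sd = 20)
    acc <- acc + p$value
  }
  expected <- cbt_profile_model(p$x, 0, 1200, 300, 0, 2, 1)
  expect_true(all(abs(acc / reps - expected) < 3 * 20 / sqrt(reps)))
})

test_that("sharp on-grid edges are recovered exactly with free density", {
  p <- generate_line_profile(5, x0 = 0, sigma = 0.01, spacing = 0.5,
                             half_length = 9)
  f <- fit_profile(p, bounds = list(sigma = c(0.005, 3)))
  expect_lt(abs(f$t - 5), 1e-3)
  expect_lt(abs(f$x0 - 0), 1e-3)
})

test_that("fixed-density fits recover noiseless thickness at clinical blur", {
  for (tt in c(1.2, 2, 3.5, 6)) {
    p <- generate_line_profile(tt, sigma = 1.0, spacing = 0.7,
                               half_length = 12)
    f <- fit_profile(p, fixed = list(y1 = 1200))
    expect_lt(abs(f$t - tt), 1e-3)
    expect_true(f$converged)
  }
})

test_that("fixed-density fit matches a brute-force grid search over the edges", {
  # oracle: hierarchical grid over (x0, t) down to 1e-4 mm with the other
  # parameters held at truth
  for (tt in c(1.5, 2, 4)) {
    p <- generate_line_profile(tt, x0 = 0.2, sigma = 1.0, spacing = 0.7,
                               half_length = 12)
    rss <- function(par) {
      sum((p$value - cbt_profile_model(p$x, 0, 1200, 300, par[1],
                                       par[2], 1.0))^2)
    }
    oracle <- zoom_grid_search(rss, lower = c(-2, 0.4), upper = c(2, 8),
                               n = 41L, levels = 4L)
    f <- fit_profile(p, fixed = list(y0 = 0, y1 = 1200, y2 = 300,
                                     sigma = 1.0))
    expect_lt(abs(f$t - oracle$par[2]), 1e-3)
    expect_lt(abs(f$x0 - oracle$par[1]), 1e-3)
  }
})

test_that("thickness below the sampling resolution is still recovered", {
  # t = 0.7 * spacing with the correct fixed density: sub-voxel regime
  sp <- 0.7
  p <- generate_line_profile(0.7 * sp, sigma = 0.9, spacing = sp,
                             half_length = 9)
  f <- fit_profile(p, fixed = list(y1 = 1200))
  expect_lt(abs(f$t - 0.7 * sp), sp)
})

test_that("profile fit rejects invalid input", {
  expect_error(fit_profile(cbt_profile(1:8, rnorm(8) + 0)), NA)
  expect_error(cbt_profile(c(1, 1, 2, 3, 4, 5, 6, 7), rep(0, 8)),
               "strictly increasing")
  expect_error(cbt_profile(1:5, rep(0, 5)), "at least 8")
})

test_that("global density estimation is a median over wide-cortex fits", {
  mk <- function(y1, t, sigma = 1, conv = TRUE)
    structure(list(y1 = y1, t = t, sigma = sigma, converged = conv),
              class = "cbt_fit")
  fits <- list(mk(1200, 6), mk(1200, 5), mk(1200, 8))
  expect_equal(estimate_global_density(fits), 1200)
  # thin-cortex and unconverged fits are excluded
  fits2 <- c(fits, list(mk(2000, 1.5), mk(2000, 6, conv = FALSE)))
  expect_equal(estimate_global_density(fits2), 1200)
  expect_error(estimate_global_density(list(mk(1200, 1))), "relax")
})

test_that("two-pass fitting is accurate on noisy benchmark-style profiles", {
  set.seed(77)
  n <- 60
  tt <- runif(n, 1, 8); sg <- runif(n, 0.6, 1.3)
  profs <- lapply(seq_len(n), function(i)
    generate_line_profile(tt[i], sigma = sg[i], spacing = 0.7,
                          half_length = 12, noise_sd = 20))
  res <- fit_profiles_two_pass(profs)
  th <- vapply(res$fits, function(f) f$t, 0)
  expect_lt(mean(abs(th - tt)), 0.3)
  expect_lt(abs(res$global_density - 1200), 0.02 * 1200)
  # no systematic bias for comfortably resolved cortices
  expect_lt(abs(mean((th - tt)[tt >= 2])), 0.1)
})
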