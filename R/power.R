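#' Density of the sample correlation coefficient under bivariate normality
#'
#' Exact sampling density of Pearson's r for samples of size `n` from a
#' bivariate normal population with correlation `rho` (Hotelling's form,
#' with the Gaussian hypergeometric factor evaluated by series):
#'
#' `f(r) = (n-2) G(n-1) (1-rho^2)^((n-1)/2) (1-r^2)^((n-4)/2) /
#'         (sqrt(2*pi) G(n-1/2) (1-rho*r)^(n-3/2)) * 2F1(1/2, 1/2; n-1/2; (1+rho*r)/2)`
#'
#' @param r numeric vector in (-1, 1).
#' @param n sample size, `>= 4`.
#' @param rho population correlation in (-1, 1).
#' @return density values at `r`.
#' @export
dcorr <- function(r, n, rho) {
  stopifnot(n >= 4, abs(rho) < 1)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  c_par <- n - 0.5
  z <- (1 + rho * r) / 2
  log_f <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(c_par) +
    ((n - 1) / 2) * log1p(-rho^2) + ((n - 4) / 2) * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r)
  exp(log_f) * .hyp2f1_half(c_par, z)
}

## 2F1(1/2, 1/2; c; z) by its power series; converges for z in [0, 1)
## (fast here because c = n - 1/2 is moderate to large).
.hyp2f1_half <- function(c_par, z) {
  out <- rep(1, length(z))
  term <- rep(1, length(z))
  k <- 0
  repeat {
    term <- term * ((0.5 + k)^2 / ((c_par + k) * (k + 1))) * z
    out <- out + term
    k <- k + 1
    if (max(abs(term)) < 1e-14 * max(out) || k > 5000) break
  }
  out
}

#' Exact power of the two-sided test of zero correlation
#'
#' Power of the level-`alpha` two-sided t-test of `rho = 0` (rejection when
#' `|r| > r_crit` with `r_crit` from the t quantile) computed by integrating
#' the exact sampling density of r under the true correlation.
#'
#' @param n sample size, `>= 4`.
#' @param rho true population correlation.
#' @param alpha two-sided significance level.
#' @return power in \[0, 1\].
#' @export
power_correlation_exact <- function(n, rho, alpha = 0.05) {
  stopifnot(n >= 4, alpha > 0, alpha < 1)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  r_crit <- tc / sqrt(tc^2 + n - 2)
  upper <- stats::integrate(dcorr, r_crit, 1, n = n, rho = rho,
                            rel.tol = 1e-10)$value
  lower <- stats::integrate(dcorr, -1, -r_crit, n = n, rho = rho,
                            rel.tol = 1e-10)$value
  min(max(upper + lower, 0), 1)
}

#' Approximate power of the correlation test via the Fisher z transform
#'
#' Normal-approximation cross-check: `atanh(r)` is treated as normal with
#' mean `atanh(rho)` and SD `1/sqrt(n-3)`.
#'
#' @inheritParams power_correlation_exact
#' @export
power_correlation_fisher <- function(n, rho, alpha = 0.05) {
  stopifnot(n >= 4, alpha > 0, alpha < 1)
  za <- stats::qnorm(1 - alpha / 2)
  m <- sqrt(n - 3) * atanh(rho)
  stats::pnorm(m - za) + stats::pnorm(-m - za)
}

#' Minimal sample size for detecting a nonzero correlation
#'
#' Smallest `n >= 4` such that the two-sided level-`alpha` test of zero
#' correlation reaches the target power at true correlation `rho`, using the
#' exact sampling distribution of r under bivariate normality (or the Fisher
#' z approximation when `method = "fisher"`).
#'
#' @param rho true correlation, nonzero, in (-1, 1).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param method `"exact"` (default) or `"fisher"`.
#' @param n_max search cap.
#' @return integer sample size.
#' @export
sample_size_for_correlation <- function(rho, alpha = 0.05, power = 0.80,
                                        method = c("exact", "fisher"),
                                        n_max = 10000L) {
  method <- match.arg(method)
  if (!is.numeric(rho) || abs(rho) >= 1 || rho == 0)
    stop("rho must be nonzero and strictly inside (-1, 1); ",
         "power against rho = 0 never exceeds alpha")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  pw <- switch(method,
               exact = power_correlation_exact,
               fisher = power_correlation_fisher)
  for (n in 4:n_max) {
    if (pw(n, rho, alpha) >= power) return(as.integer(n))
  }
  stop("target power not reached by n = ", n_max)
}
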