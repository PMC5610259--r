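#' Configuration of the Gibbs NSD error generator
#'
#' Parameters of the bivariate normal target
#' `(Y, Z) ~ N(mu1, mu2, s1^2, s2^2, rho0)` with negative correlation
#' `rho0 < 0`, from which errors `e_t = a * Y_t + b * Z_t` are produced by a
#' systematic-scan Gibbs chain.  The defaults are the simulation conditions
#' of the size and power study: `N(0, 0, 1, 16, -0.5)`, for which the
#' stationary error variance is `s1^2 + s2^2 + 2 rho0 s1 s2 = 13`.
#'
#' @param mu1,mu2 component means.
#' @param s1,s2 positive component standard deviations.
#' @param rho0 correlation in (-1, 0).
#' @param a,b positive combination weights (default 1, 1).
#' @param burn_in nonnegative number of discarded initial scans.
#' @return a list of class `"nsd_gibbs_config"`.
#' @export
nsd_gibbs_config <- function(mu1 = 0, mu2 = 0, s1 = 1, s2 = 4, rho0 = -0.5,
                             a = 1, b = 1, burn_in = 1000) {
  if (!is.finite(rho0) || rho0 <= -1 || rho0 >= 0)
    stop("'rho0' must lie in (-1, 0): negative dependence is required")
  if (s1 <= 0 || s2 <= 0) stop("'s1' and 's2' must be positive")
  if (burn_in < 0) stop("'burn_in' must be nonnegative")
  structure(list(mu1 = mu1, mu2 = mu2, s1 = s1, s2 = s2, rho0 = rho0,
                 a = a, b = b, burn_in = as.integer(burn_in)),
            class = "nsd_gibbs_config")
}

#' Stationary variance of the Gibbs NSD errors
#'
#' Closed form `a^2 s1^2 + b^2 s2^2 + 2 a b rho0 s1 s2`, the variance of
#' `a Y + b Z` under the target bivariate normal.  Equals 13 under the
#' default configuration.  This is also `E psi(e)^2` for the least-squares
#' score, the quantity estimated by [estimate_sigma2()].
#'
#' @param cfg an `"nsd_gibbs_config"`.
#' @return positive scalar.
#' @export
nsd_error_variance <- function(cfg = nsd_gibbs_config()) {
  with(cfg, a^2 * s1^2 + b^2 * s2^2 + 2 * a * b * rho0 * s1 * s2)
}

#' Generate NSD errors by Gibbs sampling
#'
#' Runs a systematic-scan Gibbs chain on the bivariate normal target:
#' `Y_t | Z_{t-1} ~ N(mu1 + rho0 (s1/s2)(Z_{t-1} - mu2), s1^2 (1 - rho0^2))`
#' then `Z_t | Y_t` analogously, initialized at `(mu1, mu2)`, and records
#' `e_t = a Y_t + b Z_t` after the burn-in.  Negatively correlated normal
#' pairs combined this way form a negatively superadditive dependent
#' sequence.  Fully reproducible given `seed`.
#'
#' @param n number of errors to return.
#' @param cfg an `"nsd_gibbs_config"`.
#' @param seed optional integer seed (uses the current RNG state when NULL).
#' @return numeric vector of length n.
#' @export
gibbs_nsd_errors <- function(n, cfg = nsd_gibbs_config(), seed = NULL) {
  stopifnot(inherits(cfg, "nsd_gibbs_config"))
  if (n < 1) stop("'n' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  total <- n + cfg$burn_in
  z_innov <- stats::rnorm(total)
  y_innov <- stats::rnorm(total)
  sy <- cfg$s1 * sqrt(1 - cfg$rho0^2)
  sz <- cfg$s2 * sqrt(1 - cfg$rho0^2)
  ry <- cfg$rho0 * cfg$s1 / cfg$s2
  rz <- cfg$rho0 * cfg$s2 / cfg$s1
  y <- numeric(total); z <- numeric(total)
  z_prev <- cfg$mu2
  for (t in seq_len(total)) {
    y[t] <- cfg$mu1 + ry * (z_prev - cfg$mu2) + sy * y_innov[t]
    z[t] <- cfg$mu2 + rz * (y[t] - cfg$mu1) + sz * z_innov[t]
    z_prev <- z[t]
  }
  keep <- (cfg$burn_in + 1):total
  cfg$a * y[keep] + cfg$b * z[keep]
}

#' Generate an exchangeable negatively associated Gaussian error vector
#'
#' Draws one vector from `N(0, Sigma)` with `Sigma = tau2 * I - c * (J - I)`:
#' every pair of components has covariance exactly `-c < 0`.  A Gaussian
#' vector with nonpositive off-diagonal covariances is negatively associated,
#' hence NSD, so this generator is the certified-NSD fixture used in
#' dependence property tests.
#'
#' @param n vector length.
#' @param tau2 positive marginal variance.
#' @param c nonnegative pairwise covariance magnitude; must satisfy
#'   `c <= tau2 / (n - 1)` for positive definiteness.
#' @param seed optional integer seed.
#' @return numeric vector of length n.
#' @export
gaussian_na_errors <- function(n, tau2 = 13, c = 0, seed = NULL) {
  if (n < 1) stop("'n' must be a positive integer")
  if (tau2 <= 0) stop("'tau2' must be positive")
  if (c < 0) stop("'c' must be nonnegative")
  if (n > 1 && c > tau2 / (n - 1))
    stop("'c' too large: covariance matrix not positive definite ",
         "(need c <= tau2 / (n - 1))")
  if (!is.null(seed)) set.seed(seed)
  if (c == 0) return(stats::rnorm(n, sd = sqrt(tau2)))
  # Sigma = (tau2 + c) I - c J: spectral draw without forming Sigma
  z <- stats::rnorm(n)
  zbar <- mean(z)
  sd_common <- sqrt(tau2 - (n - 1) * c)   # eigenvalue of the ones direction
  sd_orth <- sqrt(tau2 + c)
  sd_orth * (z - zbar) + sd_common * zbar
}

#' Dependence diagnostics for an error sequence
#'
#' Lag autocovariances and an empirical CDF grid for plotting against a
#' reference normal, as a quick check of the negative-dependence structure
#' and marginal behaviour of generated errors.
#'
#' @param errors numeric vector, or a matrix whose columns are independent
#'   replicates.
#' @param max_lag largest lag (must be < number of observations).
#' @param ecdf_points number of empirical CDF grid points.
#' @return list with `lag_cov` (data.frame lag / autocovariance, averaged
#'   over replicates for matrix input) and `ecdf` (data.frame x / F_hat /
#'   F_normal using the sample mean and sd).
#' @export
dependence_diagnostics <- function(errors, max_lag = 10, ecdf_points = 101) {
  E <- if (is.matrix(errors)) errors else matrix(errors, ncol = 1)
  n <- nrow(E)
  if (max_lag >= n) stop("'max_lag' must be smaller than the sample size")
  acov <- sapply(seq_len(max_lag), function(k) {
    mean(apply(E, 2, function(e) {
      mean((e[1:(n - k)] - mean(e)) * (e[(k + 1):n] - mean(e)))
    }))
  })
  v <- as.numeric(E)
  xs <- seq(min(v), max(v), length.out = ecdf_points)
  Fhat <- stats::ecdf(v)(xs)
  s <- stats::sd(v)
  Fn <- if (is.na(s) || s == 0) as.numeric(xs >= mean(v))
        else stats::pnorm(xs, mean(v), s)
  list(lag_cov = data.frame(lag = seq_len(max_lag), autocovariance = acov),
       ecdf = data.frame(x = xs, F_hat = Fhat, F_normal = Fn))
}
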