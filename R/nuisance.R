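#' Nuisance-parameter estimators for the M-test
#'
#' The asymptotic calibration of the M-test involves two scalars:
#' `sigma^2 = E psi(e)^2` and `lambda`, the derivative at 0 of
#' `G(u) = E psi(e + u)`.  Both are estimated from the residuals of the
#' unrestricted fit:
#' \deqn{\hat\sigma^2_n = n^{-1} \sum_t \psi^2(r_t), \qquad
#'       \hat\lambda_n = (2nh)^{-1} \sum_t \{\psi(r_t + h) - \psi(r_t - h)\},}
#' with a bandwidth h > 0.  For the least-squares score (`psi` identity)
#' `lambda_hat` equals 1 for any bandwidth and any residuals.
#'
#' @param residuals numeric residual vector (non-empty).
#' @param loss a `"loss_spec"`.
#' @param h positive bandwidth.
#' @return `estimate_sigma2`: the mean of `psi(residuals)^2`;
#'   `estimate_lambda`: the finite-difference slope estimate.
#' @export
estimate_sigma2 <- function(residuals, loss) {
  if (length(residuals) == 0) stop("empty residual vector")
  mean(psi_eval(loss, residuals)^2)
}

#' @rdname estimate_sigma2
#' @export
estimate_lambda <- function(residuals, loss, h) {
  if (length(residuals) == 0) stop("empty residual vector")
  if (!is.finite(h) || h <= 0) stop("bandwidth 'h' must be positive")
  # identity score: every difference is 2h, so the estimator is 1 analytically
  if (loss$name == "ls") return(1)
  n <- length(residuals)
  sum(psi_eval(loss, residuals + h) - psi_eval(loss, residuals - h)) / (2 * n * h)
}

#' Default bandwidth for the lambda estimator
#'
#' The bandwidth sequence must satisfy `h_n -> 0`, `h_n / sqrt(d_n) -> Inf`
#' and `lim n h_n^2 > 0`, where `d_n` is the maximum leverage.  The default
#' `h = c * d_n^{1/4}` meets all three along any design with `d_n = O(1/n)`.
#' Finite-sample surrogates of the conditions (`h / sqrt(d_n) >= 1`,
#' `n h^2 >= 1`) are checked for the instance at hand, with a warning when
#' violated.
#'
#' @param d_n maximum leverage, in (0, 1] (see [leverage_max()]).
#' @param n sample size.
#' @param c positive scale constant (default 1).
#' @return positive bandwidth.
#' @examples
#' default_bandwidth(0.01, 100)  # 0.01^(1/4) ~ 0.316
#' @export
default_bandwidth <- function(d_n, n, c = 1) {
  if (!is.finite(d_n) || d_n <= 0 || d_n > 1) stop("'d_n' must lie in (0, 1]")
  if (c <= 0) stop("'c' must be positive")
  h <- c * d_n^(1 / 4)
  if (h / sqrt(d_n) < 1)
    warning("bandwidth condition h / sqrt(d_n) >= 1 violated for this design")
  if (n * h^2 < 1)
    warning("bandwidth condition n * h^2 >= 1 violated for this design")
  h
}
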