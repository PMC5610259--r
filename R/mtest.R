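#' M-criterion: restricted minus unrestricted objective
#'
#' `M_n` is the difference between the minimized sum-of-rho objective under
#' the null restriction and the unrestricted minimum; it measures the
#' departure of the data from the null hypothesis and is nonnegative by
#' nestedness.  Differences within `-1e-8` (solver noise) are clipped to 0.
#'
#' @param fit_restricted,fit_unrestricted `"m_est"` objects fitted to the
#'   same data with the same loss.
#' @return nonnegative scalar.
#' @export
m_criterion <- function(fit_restricted, fit_unrestricted) {
  stopifnot(inherits(fit_restricted, "m_est"),
            inherits(fit_unrestricted, "m_est"))
  if (fit_restricted$n != fit_unrestricted$n ||
      fit_restricted$loss$name != fit_unrestricted$loss$name)
    stop("fits do not come from the same data / loss")
  M <- fit_restricted$objective - fit_unrestricted$objective
  if (M < -1e-8)
    warning("restricted objective below unrestricted by ", format(-M),
            "; check solver convergence")
  max(M, 0)
}

#' Equal-tail chi-square rejection region
#'
#' For significance level `alpha` and `df` degrees of freedom, returns the
#' critical values of the test.  Mode `"two_sided_equal_tail"` rejects when
#' the statistic falls below the `alpha/2` quantile or above the
#' `1 - alpha/2` quantile of the central chi-square law; mode `"upper"` is
#' the conventional one-sided test.
#'
#' @param alpha level in (0, 1).
#' @param df positive integer degrees of freedom.
#' @param mode `"two_sided_equal_tail"` or `"upper"`.
#' @return list with `lower_crit` and `upper_crit` (`lower_crit = 0` for
#'   `"upper"`).
#' @examples
#' rejection_region(0.05, 2)  # lower ~ 0.0506, upper ~ 7.378
#' @export
rejection_region <- function(alpha, df,
                             mode = c("two_sided_equal_tail", "upper")) {
  mode <- match.arg(mode)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (df < 1) stop("'df' must be a positive integer")
  if (mode == "two_sided_equal_tail")
    list(lower_crit = stats::qchisq(alpha / 2, df),
         upper_crit = stats::qchisq(1 - alpha / 2, df))
  else
    list(lower_crit = 0, upper_crit = stats::qchisq(1 - alpha, df))
}

#' Noncentrality parameter under local alternatives
#'
#' For the drifting alternatives `t(H) %*% (beta - b) = t(H) %*% omega_n`
#' the calibrated statistic is asymptotically noncentral chi-square with
#' noncentrality
#' `v(n) = lambda^2 / sigma^2 * || t(H_n) %*% S_n^{1/2} %*% omega_n ||^2`,
#' where `H_n = S_n^{-1/2} H (t(H) S_n^{-1} H)^{-1/2}` (symmetric matrix
#' square roots).
#'
#' @param lambda,sigma2 nuisance parameters (or their estimates).
#' @param hyp a `"linear_hypothesis"`.
#' @param S_n design Gram matrix `t(X) %*% X`, positive definite.
#' @param omega_n numeric p-vector of the local shift.
#' @return nonnegative scalar `v(n)`.
#' @export
noncentrality <- function(lambda, sigma2, hyp, S_n, omega_n) {
  stopifnot(inherits(hyp, "linear_hypothesis"))
  S_half <- sym_sqrt(S_n)
  S_inv_half <- sym_sqrt(S_n, inverse = TRUE)
  HSH <- crossprod(hyp$H, solve(S_n, hyp$H))
  Hn <- S_inv_half %*% hyp$H %*% sym_sqrt(HSH, inverse = TRUE)
  omega_proj <- drop(crossprod(Hn, S_half %*% omega_n))
  lambda^2 / sigma2 * sum(omega_proj^2)
}

# symmetric square root (or its inverse) of a positive definite matrix
sym_sqrt <- function(A, inverse = FALSE) {
  e <- eigen(A, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive definite")
  pow <- if (inverse) -0.5 else 0.5
  e$vectors %*% (e$values^pow * t(e$vectors))
}

#' Robust M-test of a linear hypothesis
#'
#' Tests `H0: t(H) %*% (beta - b) = 0` in the linear model
#' `y = X beta + e` with possibly negatively superadditive dependent errors.
#' The test statistic is `2 * lambda_hat * M_n / sigma2_hat`, where `M_n` is
#' the restricted-minus-unrestricted minimized objective and the nuisance
#' estimates come from the unrestricted residuals; under the null it is
#' asymptotically chi-square with `q = rank(H)` degrees of freedom.
#'
#' @inheritParams m_est
#' @param hypothesis a `"linear_hypothesis"`.
#' @param alpha significance level (default 0.05).
#' @param h bandwidth for the lambda estimator; default
#'   [default_bandwidth()] with c = 1.
#' @param region `"two_sided_equal_tail"` (default, the calibration used for
#'   the size and power studies) or `"upper"`.
#' @param use_restricted_residuals estimate the nuisances from the restricted
#'   rather than unrestricted residuals (sensitivity analysis; default FALSE).
#' @param omega_n optional local-alternative shift vector; when supplied the
#'   result carries the noncentrality `v(n)` and the theoretical power.
#' @return an object of class `"m_test"`: list with `M_n`, `lambda_hat`,
#'   `sigma2_hat`, `h`, `d_n`, `statistic`, `df`, `alpha`, `region`,
#'   `lower_crit`, `upper_crit`, `p_value`, `reject`, the two fits and,
#'   when `omega_n` is given, `noncentrality` and `power_theoretical`.
#' @examples
#' set.seed(2)
#' X <- cbind(1, runif(100, 0, 5))
#' y <- drop(X %*% c(1, 2)) + rnorm(100)
#' m_test(x = X, y = y, loss = "ls",
#'        hypothesis = linear_hypothesis(diag(2), c(1, 2)))
#' @export
m_test <- function(formula, data, x = NULL, y = NULL, loss = "ls",
                   hypothesis, alpha = 0.05, h = NULL,
                   region = c("two_sided_equal_tail", "upper"),
                   use_restricted_residuals = FALSE, omega_n = NULL,
                   sigma0 = NULL, ...) {
  region <- match.arg(region)
  stopifnot(inherits(hypothesis, "linear_hypothesis"))
  if (!missing(formula)) {
    mf <- stats::model.frame(formula, data)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    yv <- stats::model.response(mf)
  } else {
    X <- as.matrix(x); yv <- as.numeric(y)
  }
  if (is.character(loss)) {
    loss <- if (loss == "huber")
      make_loss("huber", huber_k = resolve_huber_k(X, yv, sigma0)$k)
    else make_loss(loss)
  }

  fit1 <- m_est(x = X, y = yv, loss = loss, ...)
  fit0 <- m_est(x = X, y = yv, loss = loss, restrict = hypothesis, ...)
  M_n <- m_criterion(fit0, fit1)

  lev <- leverage_max(X)
  if (is.null(h)) h <- default_bandwidth(lev$d_n, fit1$n)
  res_for_nuisance <- if (use_restricted_residuals) fit0$residuals else fit1$residuals
  sigma2_hat <- estimate_sigma2(res_for_nuisance, loss)
  lambda_hat <- estimate_lambda(res_for_nuisance, loss, h)
  if (!is.finite(lambda_hat) || lambda_hat <= 0)
    stop("estimated lambda is not positive (", format(lambda_hat),
         "); the test statistic is undefined - consider a larger bandwidth")
  if (sigma2_hat <= 0) stop("estimated sigma^2 is not positive")

  statistic <- 2 * lambda_hat * M_n / sigma2_hat
  df <- hypothesis$q
  crit <- rejection_region(alpha, df, region)
  F_s <- stats::pchisq(statistic, df)
  if (region == "two_sided_equal_tail") {
    p_value <- min(1, 2 * min(F_s, 1 - F_s))
    reject <- statistic < crit$lower_crit || statistic > crit$upper_crit
  } else {
    p_value <- 1 - F_s
    reject <- statistic > crit$upper_crit
  }

  out <- list(M_n = M_n, lambda_hat = lambda_hat, sigma2_hat = sigma2_hat,
              h = h, d_n = lev$d_n, statistic = statistic, df = df,
              alpha = alpha, region = region,
              lower_crit = crit$lower_crit, upper_crit = crit$upper_crit,
              p_value = p_value, reject = reject,
              fit_unrestricted = fit1, fit_restricted = fit0,
              hypothesis = hypothesis, loss = loss)
  if (!is.null(omega_n)) {
    v_n <- noncentrality(lambda_hat, sigma2_hat, hypothesis, lev$S_n, omega_n)
    out$noncentrality <- v_n
    out$power_theoretical <- chisq_region_power(v_n, df, crit, region)
  }
  structure(out, class = "m_test")
}

# rejection probability of the region under a noncentral chi-square
chisq_region_power <- function(ncp, df, crit, region) {
  if (region == "two_sided_equal_tail")
    stats::pchisq(crit$lower_crit, df, ncp = ncp) +
      stats::pchisq(crit$upper_crit, df, ncp = ncp, lower.tail = FALSE)
  else
    stats::pchisq(crit$upper_crit, df, ncp = ncp, lower.tail = FALSE)
}

#' @export
print.m_test <- function(x, digits = 4, ...) {
  cat("\n\tRobust M-test of a linear hypothesis\n\n")
  cat("loss: ", x$loss$name, ",  n = ", x$fit_unrestricted$n,
      ",  df = q = ", x$df, "\n", sep = "")
  cat("M_n = ", format(x$M_n, digits = digits),
      ",  lambda_hat = ", format(x$lambda_hat, digits = digits),
      ",  sigma2_hat = ", format(x$sigma2_hat, digits = digits),
      ",  h = ", format(x$h, digits = digits), "\n", sep = "")
  cat("statistic 2*lambda*M_n/sigma^2 = ", format(x$statistic, digits = digits),
      ",  p-value = ", format(x$p_value, digits = digits), "\n", sep = "")
  cat("region (", x$region, ", alpha = ", x$alpha, "): [",
      format(x$lower_crit, digits = digits), ", ",
      format(x$upper_crit, digits = digits), "] -> ",
      if (x$reject) "REJECT H0" else "do not reject H0", "\n", sep = "")
  if (!is.null(x$noncentrality))
    cat("local alternative: v(n) = ", format(x$noncentrality, digits = digits),
        ", theoretical power = ", format(x$power_theoretical, digits = digits),
        "\n", sep = "")
  invisible(x)
}
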