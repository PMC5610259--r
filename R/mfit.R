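#' Robust M-estimation of a linear model
#'
#' Fits the linear model `y = X beta + e` by minimizing
#' `sum(rho(y - X beta))` for a convex loss `rho`, optionally under the
#' linear restriction `t(H) %*% (beta - b) = 0`.  This is the single fitting
#' entry point of the package; [m_test()] builds on it.
#'
#' The restricted fit is obtained by the null-space reparameterization
#' `beta = b + K %*% gamma` with K an orthonormal basis of the null space of
#' `t(H)`, i.e. an unrestricted fit of `y - X b` on `X %*% K`.  When q = p
#' the restriction pins `beta = b` exactly and no optimization is needed.
#'
#' @param formula,data a model formula and data frame (standard interface);
#'   alternatively supply `x` and `y` directly.
#' @param x numeric n x p design matrix (used when `formula` is missing).
#' @param y numeric response vector.
#' @param loss a `"loss_spec"` from [make_loss()], or one of the strings
#'   `"ls"`, `"lad"`, `"huber"`.  For the string `"huber"` the tuning constant
#'   is resolved as `1.345 * sigma0` via [resolve_huber_k()].
#' @param restrict optional `"linear_hypothesis"`; when supplied the fit
#'   satisfies `t(H) %*% (coef - b) = 0`.
#' @param sigma0 optional error scale used only to resolve the Huber constant.
#' @param ... further arguments passed to the internal solver (e.g. `tol`,
#'   `maxit`).
#' @return an object of class `"m_est"`: list with components `coefficients`,
#'   `residuals`, `fitted.values`, `objective` (the minimized sum of rho),
#'   `loss`, `restricted`, `hypothesis`, `converged`, `iterations`,
#'   `nonunique`, `n`, `p` and, for formula fits, `terms`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(50, 0, 5))
#' d$y <- 1 + 2 * d$x + rnorm(50)
#' fit <- m_est(y ~ x, d, loss = "huber")
#' coef(fit)
#' @export
m_est <- function(formula, data, x = NULL, y = NULL, loss = "ls",
                  restrict = NULL, sigma0 = NULL, ...) {
  cl <- match.call()
  trms <- NULL
  if (!missing(formula)) {
    mf <- stats::model.frame(formula, data)
    trms <- attr(mf, "terms")
    X <- stats::model.matrix(trms, mf)
    yv <- stats::model.response(mf)
  } else {
    if (is.null(x) || is.null(y)) stop("supply either 'formula' or 'x' and 'y'")
    X <- as.matrix(x)
    yv <- as.numeric(y)
  }
  n <- nrow(X); p <- ncol(X)
  if (length(yv) != n) stop("length(y) must equal nrow(x)")
  if (n <= p) stop("need n > p observations (n = ", n, ", p = ", p, ")")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (is.character(loss)) {
    loss <- if (loss == "huber")
      make_loss("huber", huber_k = resolve_huber_k(X, yv, sigma0)$k)
    else make_loss(loss)
  }
  stopifnot(inherits(loss, "loss_spec"))

  if (is.null(restrict)) {
    sol <- solve_m(X, yv, loss, ...)
    beta <- sol$beta
  } else {
    stopifnot(inherits(restrict, "linear_hypothesis"))
    if (restrict$p != p) stop("hypothesis dimension p = ", restrict$p,
                              " does not match design p = ", p)
    if (restrict$q == p) {
      beta <- restrict$b
      sol <- list(iterations = 0L, converged = TRUE, nonunique = FALSE)
    } else {
      XK <- X %*% restrict$K
      yb <- yv - drop(X %*% restrict$b)
      sol <- solve_m(XK, yb, loss, ...)
      beta <- restrict$b + drop(restrict$K %*% sol$beta)
    }
  }
  res <- yv - drop(X %*% beta)
  # LAD basic solutions interpolate p observations; their residuals are zero
  # by construction, so snap away the last-bit rounding of X %*% beta
  if (!is.null(sol$zero_idx) && length(sol$zero_idx)) {
    snap <- sol$zero_idx[abs(res[sol$zero_idx]) < 1e-8 * max(1, max(abs(yv)))]
    res[snap] <- 0
  }
  out <- structure(list(
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    residuals = res,
    fitted.values = drop(X %*% beta),
    objective = sum(loss$rho(res)),
    loss = loss,
    restricted = !is.null(restrict),
    hypothesis = restrict,
    converged = sol$converged,
    iterations = sol$iterations,
    nonunique = sol$nonunique,
    n = n, p = p,
    X = X, y = yv,
    terms = trms, call = cl), class = "m_est")
  if (!sol$converged)
    warning("M-estimation did not converge in ", sol$iterations, " iterations")
  out
}

#' Unrestricted M-fit (matrix interface)
#'
#' Convenience wrappers over [m_est()] mirroring the two estimation modes.
#' @inheritParams m_est
#' @param X numeric design matrix.
#' @param hyp a `"linear_hypothesis"`.
#' @return an `"m_est"` object.
#' @export
fit_m <- function(X, y, loss = "ls", ...) m_est(x = X, y = y, loss = loss, ...)

#' @rdname fit_m
#' @export
fit_m_restricted <- function(X, y, loss = "ls", hyp, ...)
  m_est(x = X, y = y, loss = loss, restrict = hyp, ...)

#' Maximum leverage and design Gram matrix
#'
#' Computes `S_n = t(X) %*% X` and the leverage bound
#' `d_n = max_t x_t' S_n^{-1} x_t`, the quantity whose O(1/n) decay the
#' asymptotic theory assumes.  The hat diagonal sums to p, which is used as an
#' internal consistency check.
#'
#' @param X numeric n x p design matrix with positive definite `t(X) %*% X`.
#' @return list with `d_n` (in (0, 1]) and `S_n`.
#' @export
leverage_max <- function(X) {
  X <- as.matrix(X)
  S_n <- crossprod(X)
  R <- tryCatch(chol(S_n), error = function(e)
    stop("S_n = t(X) X is not positive definite"))
  # hat diagonal via backsolve: h_t = || R^{-T} x_t ||^2
  B <- backsolve(R, t(X), transpose = TRUE)
  h <- colSums(B^2)
  if (abs(sum(h) - ncol(X)) > 1e-8 * ncol(X))
    warning("hat-diagonal trace check failed: sum = ", sum(h))
  list(d_n = max(h), S_n = S_n)
}

#' @export
print.m_est <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat(if (x$restricted) "Restricted" else "Unrestricted",
      " M-fit (loss: ", x$loss$name, ")\n", sep = "")
  cat("Coefficients:\n")
  print.default(format(stats::coef(x), digits = digits), print.gap = 2L,
                quote = FALSE)
  cat("Objective (sum rho): ", format(x$objective, digits = digits), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.m_est <- function(object, ...) {
  r <- object$residuals
  structure(list(fit = object,
                 resid_summary = summary(r),
                 scale_mad = stats::median(abs(r - stats::median(r))) / 0.6745,
                 n_zero_resid = sum(r == 0)),
            class = "summary.m_est")
}

#' @export
print.summary.m_est <- function(x, ...) {
  print(x$fit)
  cat("Residuals:\n"); print(x$resid_summary)
  cat("MAD scale: ", format(x$scale_mad, digits = 4),
      "; exactly-zero residuals: ", x$n_zero_resid, "\n", sep = "")
  invisible(x)
}

#' @export
coef.m_est <- function(object, ...) object$coefficients

#' @export
residuals.m_est <- function(object, ...) object$residuals

#' @export
fitted.m_est <- function(object, ...) object$fitted.values

#' @export
predict.m_est <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (!is.null(object$terms)) {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  } else {
    X <- as.matrix(newdata)
  }
  drop(X %*% object$coefficients)
}

#' @export
plot.m_est <- function(x, ...) {
  graphics::hist(x$residuals, breaks = "FD", freq = FALSE,
                 main = paste0("M-fit residuals (", x$loss$name, ")"),
                 xlab = "residual", ...)
  invisible(x)
}
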