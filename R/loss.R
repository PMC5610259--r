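#' Construct a convex loss specification
#'
#' Builds the loss function \eqn{\rho} and its score \eqn{\psi} used by the
#' M-estimators and the M-test.  \eqn{\rho} must be convex; \eqn{\psi} is a
#' selection between the left and right derivatives of \eqn{\rho}, hence
#' non-decreasing.  Built-ins:
#' \describe{
#'   \item{`ls`}{\eqn{\rho(x) = x^2/2}, \eqn{\psi(x) = x} (least squares).}
#'   \item{`lad`}{\eqn{\rho(x) = |x|}, \eqn{\psi(x) = \mathrm{sign}(x)} with
#'     the convention \eqn{\psi(0) = 0} (least absolute deviation).}
#'   \item{`huber`}{\eqn{\rho(x) = x^2/2} for \eqn{|x| \le k}, else
#'     \eqn{k|x| - k^2/2}; \eqn{\psi(x) = \max(-k, \min(x, k))}.}
#' }
#'
#' @param name one of `"ls"`, `"lad"`, `"huber"`, `"custom"`.
#' @param huber_k positive tuning constant for the Huber loss.  The
#'   conventional choice is `1.345 * sigma0` where `sigma0` is an error scale;
#'   see [resolve_huber_k()].
#' @param rho,psi for `name = "custom"`, vectorized functions giving the loss
#'   and its (non-decreasing) score.  A convexity spot-check is run on a grid
#'   and failures raise a warning, not an error.
#' @return an object of class `"loss_spec"`: a list with elements `name`,
#'   `rho`, `psi` and `tuning`.
#' @examples
#' hub <- make_loss("huber", huber_k = 1)
#' hub$rho(2)    # 1.5
#' hub$psi(-2)   # -1
#' @export
make_loss <- function(name = c("ls", "lad", "huber", "custom"),
                      huber_k = NULL, rho = NULL, psi = NULL) {
  name <- match.arg(name)
  tuning <- list()
  if (name == "ls") {
    rho <- function(u) u^2 / 2
    psi <- function(u) u
  } else if (name == "lad") {
    rho <- function(u) abs(u)
    psi <- function(u) sign(u)   # sign(0) = 0: midpoint of the subgradient
  } else if (name == "huber") {
    if (is.null(huber_k) || !is.finite(huber_k) || huber_k <= 0)
      stop("huber loss requires a positive 'huber_k'")
    k <- huber_k
    rho <- function(u) ifelse(abs(u) <= k, u^2 / 2, k * abs(u) - k^2 / 2)
    psi <- function(u) pmax(-k, pmin(u, k))
    tuning$huber_k <- k
  } else {
    if (is.null(rho) || is.null(psi))
      stop("custom loss requires both 'rho' and 'psi'")
    chk <- check_convexity(rho)
    if (!chk) warning("custom 'rho' failed a convexity spot-check; ",
                      "the M-test theory requires a convex loss")
  }
  structure(list(name = name, rho = rho, psi = psi, tuning = tuning),
            class = "loss_spec")
}

# Spot-check convexity of a scalar function on a grid.
check_convexity <- function(rho, grid = seq(-10, 10, length.out = 81),
                            tol = 1e-8) {
  v <- rho(grid)
  if (any(!is.finite(v))) return(FALSE)
  # midpoint convexity on consecutive triples
  mid <- rho((grid[-c(1, 2)] + grid[1:(length(grid) - 2)]) / 2)
  all(mid <= (v[-c(1, 2)] + v[1:(length(v) - 2)]) / 2 + tol)
}

#' Evaluate the loss or its score
#'
#' Thin wrappers around the `rho` and `psi` members of a [make_loss()]
#' specification, with input validation.
#'
#' @param loss a `"loss_spec"` object.
#' @param u numeric vector of evaluation points; must be finite.
#' @return numeric vector of the same length as `u`.
#' @export
rho_eval <- function(loss, u) {
  stopifnot(inherits(loss, "loss_spec"))
  if (any(!is.finite(u))) stop("'u' must be finite")
  loss$rho(u)
}

#' @rdname rho_eval
#' @export
psi_eval <- function(loss, u) {
  stopifnot(inherits(loss, "loss_spec"))
  if (any(!is.finite(u))) stop("'u' must be finite")
  loss$psi(u)
}

#' Resolve the Huber tuning constant from an error scale
#'
#' The Huber constant is taken as `1.345 * sigma0`.  When `sigma0` is not
#' supplied it is estimated robustly as the median absolute deviation of
#' preliminary least-squares residuals divided by 0.6745.
#'
#' @param X,y design matrix and response used for the preliminary LS fit.
#' @param sigma0 optional known error scale; overrides estimation.
#' @return a list with elements `k` and `sigma0`.
#' @export
resolve_huber_k <- function(X, y, sigma0 = NULL) {
  if (is.null(sigma0)) {
    r <- stats::lm.fit(X, y)$residuals
    sigma0 <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (sigma0 <= 0) sigma0 <- stats::sd(r)
  }
  list(k = 1.345 * sigma0, sigma0 = sigma0)
}

#' @export
print.loss_spec <- function(x, ...) {
  cat("M-estimation loss: ", x$name, "\n", sep = "")
  if (length(x$tuning))
    cat("  tuning: ",
        paste(names(x$tuning), unlist(x$tuning), sep = " = ", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
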