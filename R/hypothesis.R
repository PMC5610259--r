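#' Orthonormal basis of the null space of t(H)
#'
#' Returns a p x (p - q) matrix K with orthonormal columns such that
#' `t(H) %*% K = 0`.  The basis is computed from the full QR decomposition of
#' H with a fixed sign convention (first nonzero entry of each column made
#' positive), so the result is deterministic for a given H.
#'
#' @param H numeric p x q matrix of full column rank q, 1 <= q <= p.
#' @return a p x (p - q) matrix; zero-column matrix when q = p.
#' @export
nullspace_basis <- function(H) {
  H <- as.matrix(H)
  p <- nrow(H); q <- ncol(H)
  if (q < 1 || q > p) stop("H must be p x q with 1 <= q <= p")
  qr_H <- qr(H)
  if (qr_H$rank < q) stop("H is rank deficient: rank ", qr_H$rank, " < q = ", q)
  if (q == p) return(matrix(0, p, 0))
  K <- qr.Q(qr_H, complete = TRUE)[, (q + 1):p, drop = FALSE]
  # fixed sign convention for determinism
  for (j in seq_len(ncol(K))) {
    i <- which(abs(K[, j]) > 1e-12)[1]
    if (!is.na(i) && K[i, j] < 0) K[, j] <- -K[, j]
  }
  K
}

#' Specify a linear hypothesis on regression coefficients
#'
#' Represents the null hypothesis `t(H) %*% (beta - b) = 0`, where H is a
#' known p x q matrix of rank q and b a known p-vector.  The object carries
#' the orthonormal null-space basis K of `t(H)` used to reparameterize the
#' restricted fit as `beta = b + K %*% gamma`.
#'
#' @param H numeric p x q matrix of full column rank (a vector is treated as
#'   a single column).
#' @param b numeric p-vector.
#' @return an object of class `"linear_hypothesis"` with elements `H`, `b`,
#'   `K`, `p` and `q`.
#' @examples
#' linear_hypothesis(diag(2), b = c(1, 2))  # fully pinned: beta = (1, 2)
#' @export
linear_hypothesis <- function(H, b) {
  H <- as.matrix(H)
  b <- as.numeric(b)
  if (nrow(H) != length(b)) stop("nrow(H) must equal length(b)")
  K <- nullspace_basis(H)
  structure(list(H = H, b = b, K = K, p = nrow(H), q = ncol(H)),
            class = "linear_hypothesis")
}

#' @export
print.linear_hypothesis <- function(x, ...) {
  cat("Linear hypothesis t(H) (beta - b) = 0 with p = ", x$p,
      ", q = ", x$q, "\n", sep = "")
  invisible(x)
}
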