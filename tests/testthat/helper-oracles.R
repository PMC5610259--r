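# Independent oracles used by the tests.

# Two-parameter argmin of sum(rho(y - X b)) by dense grid search: a coarse
# pass over `lims`, then a fine pass (step `fine`) around the coarse argmin.
grid_argmin_2d <- function(X, y, rho, lims = c(-5, 5, -5, 5),
                           coarse = 0.05, fine = 1e-3) {
  scan <- function(b1s, b2s) {
    G <- as.matrix(expand.grid(b1 = b1s, b2 = b2s))
    obj <- colSums(matrix(rho(y - X %*% t(G)), nrow = length(y)))
    G[which.min(obj), ]
  }
  b <- scan(seq(lims[1], lims[2], by = coarse),
            seq(lims[3], lims[4], by = coarse))
  scan(seq(b[1] - 2 * coarse, b[1] + 2 * coarse, by = fine),
       seq(b[2] - 2 * coarse, b[2] + 2 * coarse, by = fine))
}

# Lagrange closed form of equality-constrained least squares:
# min ||y - X beta||^2  subject to  t(H) (beta - b) = 0
constrained_ls_oracle <- function(X, y, H, b) {
  S <- crossprod(X)
  beta_hat <- solve(S, crossprod(X, y))
  drop(beta_hat - solve(S, H) %*%
         solve(crossprod(H, solve(S, H)), crossprod(H, beta_hat - b)))
}

# small random regression instance
random_instance <- function(n = 30, p = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta)
}
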