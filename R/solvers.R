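# Internal solvers for min_beta sum(rho(y - X beta)).
#
# ls    : QR (exact).
# lad   : smoothed IRLS (Lawson weights 1/max(|r|, delta)) followed by an
#         exact vertex polish: an LAD optimum interpolates at least p
#         observations, so the fit is refined to the best exactly
#         interpolating p-subset among the observations with the smallest
#         absolute residuals.  This reproduces the basic-solution behaviour
#         of the LAD linear program (>= p zero residuals, exact objective).
# huber : IRLS with weights psi(r)/r, LS start.
# custom: BFGS on the objective with gradient -t(X) psi(r), LS start.

solve_ls <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(beta = unname(fit$coefficients), iterations = 0L, converged = TRUE,
       nonunique = FALSE)
}

solve_huber_irls <- function(X, y, loss, tol = 1e-10, maxit = 200L) {
  beta <- solve_ls(X, y)$beta
  conv <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    w <- ifelse(r == 0, 1, loss$psi(r) / r)
    w <- pmax(w, 1e-12)
    beta_new <- unname(stats::lm.wfit(X, y, w)$coefficients)
    rel <- sqrt(sum((beta_new - beta)^2)) / max(1, sqrt(sum(beta^2)))
    beta <- beta_new
    if (rel < tol) { conv <- TRUE; break }
  }
  list(beta = beta, iterations = it, converged = conv, nonunique = FALSE)
}

solve_lad <- function(X, y, tol = 1e-9, maxit = 100L, delta = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  beta <- solve_ls(X, y)$beta
  obj <- function(b) sum(abs(y - drop(X %*% b)))
  it <- 0L
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    w <- 1 / pmax(abs(r), delta)
    beta_new <- unname(stats::lm.wfit(X, y, w)$coefficients)
    rel <- sqrt(sum((beta_new - beta)^2)) / max(1, sqrt(sum(beta^2)))
    beta <- beta_new
    if (rel < tol) break
  }
  # vertex polish: an optimum interpolates p observations, so scan exact
  # fits through p-subsets of the observations with smallest |residual|
  best <- beta; best_obj <- obj(beta)
  nonunique <- FALSE
  at_vertex <- FALSE
  tol_eq <- function(o) 1e-9 * max(1, o)
  repeat {
    r <- y - drop(X %*% best)
    m <- min(n, 2L * p + 2L)
    cand <- order(abs(r))[seq_len(m)]
    subs <- utils::combn(cand, p)
    vbest <- NULL; vbest_obj <- Inf
    for (j in seq_len(ncol(subs))) {
      idx <- subs[, j]
      Xs <- X[idx, , drop = FALSE]
      if (abs(det(Xs)) < 1e-12 * max(1, max(abs(Xs)))^p) next
      bj <- tryCatch(solve(Xs, y[idx]), error = function(e) NULL)
      if (is.null(bj)) next
      oj <- obj(bj)
      if (oj < vbest_obj - tol_eq(oj)) {
        vbest <- unname(bj); vbest_obj <- oj
      } else if (!is.null(vbest) && abs(oj - vbest_obj) <= tol_eq(oj) &&
                 any(abs(bj - vbest) > 1e-8)) {
        nonunique <- TRUE
      }
    }
    if (is.null(vbest)) break
    if (vbest_obj < best_obj - tol_eq(best_obj)) {
      best <- vbest; best_obj <- vbest_obj; at_vertex <- TRUE
    } else if (!at_vertex && vbest_obj <= best_obj + tol_eq(best_obj)) {
      # equal objective: prefer the exact vertex (basic) solution
      best <- vbest; best_obj <- vbest_obj; at_vertex <- TRUE
    } else break
  }
  zero_idx <- which(abs(y - drop(X %*% best)) < 1e-8 * max(1, max(abs(y))))
  list(beta = best, iterations = it, converged = TRUE, nonunique = nonunique,
       zero_idx = zero_idx)
}

solve_custom <- function(X, y, loss, maxit = 500L) {
  fn <- function(b) sum(loss$rho(y - drop(X %*% b)))
  gr <- function(b) -drop(crossprod(X, loss$psi(y - drop(X %*% b))))
  start <- solve_ls(X, y)$beta
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  list(beta = unname(opt$par), iterations = opt$counts[["function"]],
       converged = opt$convergence == 0, nonunique = FALSE)
}

solve_m <- function(X, y, loss, ...) {
  switch(loss$name,
         ls = solve_ls(X, y),
         lad = solve_lad(X, y, ...),
         huber = solve_huber_irls(X, y, loss, ...),
         solve_custom(X, y, loss, ...))
}
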