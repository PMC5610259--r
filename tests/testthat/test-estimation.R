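test_that("intercept-only fits recover mean (LS) and median (LAD)", {
  X <- matrix(1, 3, 1)
  expect_equal(unname(coef(fit_m(X, c(1, 2, 3), "ls"))), 2)
  expect_equal(unname(coef(fit_m(X, c(1, 2, 10), "lad"))), 2)
})

test_that("LS fit matches the normal equations and Huber the grid oracle", {
  set.seed(21)
  X <- cbind(1, rnorm(40)); y <- drop(X %*% c(1, -2)) + rnorm(40)
  expect_equal(unname(coef(fit_m(X, y, "ls"))),
               unname(drop(solve(crossprod(X), crossprod(X, y)))),
               tolerance = 1e-8)

  Xh <- cbind(1, 0:3); yh <- c(0, 1, 2, 10)
  hub <- make_loss("huber", huber_k = 1)
  beta_grid <- grid_argmin_2d(Xh, yh, hub$rho)
  f_hub <- fit_m(Xh, yh, hub)
  # the optimum here is a flat face (all scores saturated), so compare the
  # minimized objective against the grid oracle rather than the coordinates
  expect_equal(f_hub$objective,
               sum(hub$rho(yh - drop(Xh %*% beta_grid))), tolerance = 2e-3)
  expect_lte(f_hub$objective,
             sum(hub$rho(yh - drop(Xh %*% beta_grid))) + 2e-3)
  # LAD on the same toy against the grid oracle (objective comparison:
  # the argmin may be non-unique at a vertex)
  lad <- make_loss("lad")
  beta_grid_lad <- grid_argmin_2d(Xh, yh, lad$rho)
  f_lad <- fit_m(Xh, yh, "lad")
  expect_lte(f_lad$objective,
             sum(lad$rho(yh - drop(Xh %*% beta_grid_lad))) + 5e-3)
})

test_that("restricted fits honour the constraint and nest the objective", {
  set.seed(22)
  X <- cbind(1, runif(60, 0, 5)); y <- drop(X %*% c(1, 2)) + rnorm(60)
  # fully pinned hypothesis returns b for every loss
  hyp_full <- linear_hypothesis(diag(2), c(1, 2))
  for (l in c("ls", "lad", "huber")) {
    f0 <- fit_m_restricted(X, y, l, hyp_full)
    expect_identical(unname(coef(f0)), c(1, 2))
    f1 <- fit_m(X, y, l)
    expect_gte(f0$objective - f1$objective, -1e-8)
  }
  # partial restriction: equals the Lagrange closed form for LS
  hyp <- linear_hypothesis(c(0, 1), c(0, 0))  # beta_2 = 0
  f0 <- fit_m_restricted(X, y, "ls", hyp)
  expect_equal(unname(coef(f0)),
               constrained_ls_oracle(X, y, hyp$H, hyp$b), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(hyp$H, coef(f0) - hyp$b))), 1e-8)
  # objective invariant recomputes
  expect_equal(f0$objective, sum(make_loss("ls")$rho(residuals(f0))),
               tolerance = 1e-8)
})

test_that("restricted-minus-unrestricted objective is nonnegative on random instances", {
  set.seed(23)
  for (i in 1:200) {
    inst <- random_instance(n = 25)
    l <- sample(c("ls", "lad", "huber"), 1)
    hyp <- linear_hypothesis(matrix(rnorm(2), 2, 1), rnorm(2))
    f1 <- fit_m(inst$X, inst$y, l)
    f0 <- fit_m_restricted(inst$X, inst$y, l, hyp)
    expect_gte(f0$objective - f1$objective, -1e-8)
  }
})

test_that("M-fits are equivariant under reparameterization of the design", {
  set.seed(24)
  inst <- random_instance(n = 50)
  A <- matrix(c(2, 1, 0.5, -1), 2, 2)
  for (l in c("ls", "huber")) {
    b1 <- coef(fit_m(inst$X, inst$y, l))
    b2 <- coef(fit_m(inst$X %*% A, inst$y, l))
    expect_equal(unname(drop(A %*% b2)), unname(b1), tolerance = 1e-6)
  }
  # LAD: the minimized objective is equivariant even if the argmin is not unique
  o1 <- fit_m(inst$X, inst$y, "lad")$objective
  o2 <- fit_m(inst$X %*% A, inst$y, "lad")$objective
  expect_equal(o1, o2, tolerance = 1e-7)
})

test_that("LAD optimum is a basic solution with >= p zero residuals", {
  set.seed(25)
  for (i in 1:20) {
    inst <- random_instance(n = 40)
    f <- fit_m(inst$X, inst$y, "lad")
    expect_gte(sum(residuals(f) == 0), 2)
  }
})

test_that("degenerate designs are hard errors", {
  expect_error(fit_m(matrix(1, 2, 2), c(1, 2), "ls"))
  X <- cbind(1, c(1, 1, 1, 1))
  expect_error(fit_m(X, 1:4, "ls"), "rank deficient")
  expect_error(m_est(x = cbind(1, 1:3), y = 1:2), "length")
})

test_that("custom convex losses are fitted by gradient descent", {
  set.seed(26)
  inst <- random_instance(n = 60)
  # pseudo-Huber: smooth convex, close to Huber k=1
  cust <- make_loss("custom",
                    rho = function(u) sqrt(1 + u^2) - 1,
                    psi = function(u) u / sqrt(1 + u^2))
  f <- fit_m(inst$X, inst$y, cust)
  expect_true(f$converged)
  # gradient at optimum ~ 0
  g <- drop(crossprod(inst$X, cust$psi(residuals(f))))
  expect_lt(max(abs(g)), 1e-5)
})

test_that("leverage bound and trace identity hold", {
  lev <- leverage_max(matrix(1, 50, 1))
  expect_equal(lev$d_n, 0.02)                      # 1/n for the ones design
  expect_equal(leverage_max(diag(3))$d_n, 1)       # orthonormal rows
  set.seed(27)
  X <- cbind(1, rnorm(100))
  lev <- leverage_max(X)
  h <- diag(X %*% solve(lev$S_n, t(X)))
  expect_equal(sum(h), 2, tolerance = 1e-10)       # trace identity
  expect_equal(lev$d_n, max(h), tolerance = 1e-10)
  expect_error(leverage_max(matrix(0, 3, 2)), "positive definite")
})

test_that("formula interface, predict and summary work end to end", {
  set.seed(28)
  d <- data.frame(x = runif(80, 0, 5))
  d$y <- 1 + 2 * d$x + rnorm(80)
  f <- m_est(y ~ x, d, loss = "huber")
  expect_named(coef(f), c("(Intercept)", "x"))
  expect_equal(predict(f, data.frame(x = 0)), unname(coef(f)[1]),
               tolerance = 1e-10, ignore_attr = TRUE)
  s <- summary(f)
  expect_s3_class(s, "summary.m_est")
  expect_output(print(s), "MAD scale")
  expect_output(print(f), "Huber|huber")
})
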