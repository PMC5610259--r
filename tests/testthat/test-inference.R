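test_that("M-criterion is the nested objective difference, clipped at solver noise", {
  set.seed(41)
  X <- cbind(1, runif(30, 0, 5)); y <- drop(X %*% c(1, 2)) + rnorm(30)
  f1 <- fit_m(X, y, "ls")
  # hypothesis at the unrestricted optimum: M_n = 0
  hyp_hat <- linear_hypothesis(diag(2), unname(coef(f1)))
  f0 <- fit_m_restricted(X, y, "ls", hyp_hat)
  expect_equal(m_criterion(f0, f1), 0)
  # LS: M_n = (RSS0 - RSS1) / 2, by direct arithmetic on a 5-point toy
  Xt <- cbind(1, c(0, 1, 2, 3, 4)); yt <- c(0.2, 1.1, 1.9, 3.2, 3.9)
  hyp <- linear_hypothesis(diag(2), c(0, 1))
  f1t <- fit_m(Xt, yt, "ls"); f0t <- fit_m_restricted(Xt, yt, "ls", hyp)
  rss0 <- sum((yt - drop(Xt %*% c(0, 1)))^2)
  rss1 <- sum(residuals(f1t)^2)
  expect_equal(m_criterion(f0t, f1t), (rss0 - rss1) / 2, tolerance = 1e-10)
  # mismatched fits are rejected
  expect_error(m_criterion(fit_m(Xt, yt, "lad"), f1t), "same data / loss")
})

test_that("equal-tail rejection region matches chi-square quantiles", {
  r <- rejection_region(0.05, 2)
  expect_equal(r$lower_crit, 0.0506, tolerance = 1e-3)
  expect_equal(r$upper_crit, 7.378, tolerance = 1e-3)
  r1 <- rejection_region(0.05, 1)
  expect_equal(r1$lower_crit, 0.000982, tolerance = 1e-2)
  expect_equal(r1$upper_crit, 5.024, tolerance = 1e-3)
  # alpha -> 1: the region covers the whole positive axis
  r9 <- rejection_region(1 - 1e-12, 2)
  expect_gt(r9$lower_crit, r9$upper_crit * 0.999999)
  ru <- rejection_region(0.05, 2, "upper")
  expect_equal(ru$lower_crit, 0)
  expect_equal(ru$upper_crit, qchisq(0.95, 2))
  expect_error(rejection_region(1.2, 2), "0, 1")
})

test_that("the LS statistic reduces to Delta-RSS over the mean squared residual", {
  set.seed(42)
  X <- cbind(1, runif(200, 0, 5)); y <- drop(X %*% c(1, 2)) + rnorm(200, sd = 2)
  hyp <- linear_hypothesis(diag(2), c(1, 2))
  tst <- m_test(x = X, y = y, loss = "ls", hypothesis = hyp)
  rss1 <- sum(residuals(tst$fit_unrestricted)^2)
  rss0 <- sum(residuals(tst$fit_restricted)^2)
  expect_equal(tst$lambda_hat, 1)
  expect_equal(tst$statistic, (rss0 - rss1) / (rss1 / 200), tolerance = 1e-8)
  # statistic recomputes from its parts
  expect_equal(tst$statistic, 2 * tst$lambda_hat * tst$M_n / tst$sigma2_hat,
               tolerance = 1e-10)
  expect_equal(tst$df, 2)
  expect_true(tst$p_value >= 0 && tst$p_value <= 1)
  expect_output(print(tst), "Robust M-test")
})

test_that("the calibrated statistic is invariant to rescaling the loss", {
  set.seed(43)
  X <- cbind(1, runif(80, 0, 5)); y <- drop(X %*% c(1, 2)) + rnorm(80, sd = 3)
  hyp <- linear_hypothesis(diag(2), c(1, 2))
  k <- 1.5; cc <- 3.7
  base <- make_loss("huber", huber_k = k)
  scaled <- make_loss("custom",
                      rho = function(u) cc * base$rho(u),
                      psi = function(u) cc * base$psi(u))
  t1 <- m_test(x = X, y = y, loss = base, hypothesis = hyp, h = 0.3)
  t2 <- m_test(x = X, y = y, loss = scaled, hypothesis = hyp, h = 0.3)
  expect_equal(t2$M_n, cc * t1$M_n, tolerance = 1e-5)
  expect_equal(t2$sigma2_hat, cc^2 * t1$sigma2_hat, tolerance = 1e-5)
  expect_equal(t2$lambda_hat, cc * t1$lambda_hat, tolerance = 1e-5)
  expect_equal(t2$statistic, t1$statistic, tolerance = 1e-4)
})

test_that("noncentrality follows the projected-shift formula", {
  set.seed(44)
  S <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  hyp <- linear_hypothesis(matrix(rnorm(10), 5, 2), rnorm(5))
  # zero shift
  expect_equal(noncentrality(0.8, 2, hyp, S, rep(0, 5)), 0)
  # q = p, S = I: v(n) = lambda^2/sigma^2 ||omega||^2 (H_n orthogonal)
  hyp_full <- linear_hypothesis(diag(3), rep(0, 3))
  w <- rnorm(3)
  expect_equal(noncentrality(1, 1, hyp_full, diag(3), w), sum(w^2),
               tolerance = 1e-10)
  # invariance to right-multiplication of H by an invertible q x q matrix
  w5 <- rnorm(5)
  A <- matrix(c(2, 0.3, -1, 1.4), 2, 2)
  hyp2 <- linear_hypothesis(hyp$H %*% A, hyp$b)
  v1 <- noncentrality(0.7, 3, hyp, S, w5)
  v2 <- noncentrality(0.7, 3, hyp2, S, w5)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("m_test validates nuisance estimates and propagates options", {
  set.seed(45)
  X <- cbind(1, runif(50, 0, 5)); y <- drop(X %*% c(1, 2)) + rnorm(50)
  hyp <- linear_hypothesis(diag(2), c(1, 2))
  # a loss whose score is flat around the residuals gives lambda = 0 -> error
  flat <- make_loss("custom",
                    rho = function(u) pmax(0, abs(u) - 50),
                    psi = function(u) sign(u) * (abs(u) > 50))
  expect_error(m_test(x = X, y = y, loss = flat, hypothesis = hyp, h = 0.1),
               "lambda")
  tu <- m_test(x = X, y = y, loss = "ls", hypothesis = hyp, region = "upper")
  expect_equal(tu$lower_crit, 0)
  expect_equal(tu$p_value, pchisq(tu$statistic, 2, lower.tail = FALSE))
  # restricted-residual sensitivity switch runs
  tr <- m_test(x = X, y = y, loss = "ls", hypothesis = hyp,
               use_restricted_residuals = TRUE)
  expect_s3_class(tr, "m_test")
  # local alternative reporting
  ta <- m_test(x = X, y = y, loss = "ls", hypothesis = hyp,
               omega_n = c(0.1, 0))
  expect_gte(ta$noncentrality, 0)
  expect_true(ta$power_theoretical >= 0 && ta$power_theoretical <= 1)
})

test_that("under iid Gaussian errors the q = 1 LS statistic is chi-square(1)", {
  set.seed(46)
  n <- 400; reps <- 1000
  X <- cbind(1, runif(n, 0, 5))
  hyp <- linear_hypothesis(c(0, 1), c(0, 2))  # slope = 2, q = 1
  stats <- replicate(reps, {
    y <- drop(X %*% c(1, 2)) + rnorm(n)
    m_test(x = X, y = y, loss = "ls", hypothesis = hyp)$statistic
  })
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})
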