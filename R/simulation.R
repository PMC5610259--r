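#' Random explanatory-variable designs for the Monte Carlo study
#'
#' Generates the n x 2 design (intercept plus one covariate) used in the
#' size and power study:
#' \describe{
#'   \item{Model I}{`x_t = 5 u_t`}
#'   \item{Model II}{`x_t = sin(2 t) + 1.5 u_t` (t = 1..n, radians)}
#' }
#' with `u_t` standard uniform.
#'
#' @param n number of rows (>= 2).
#' @param model `"I"` or `"II"`.
#' @param seed optional integer seed.
#' @return numeric n x 2 matrix with columns `(Intercept)` and `x`.
#' @export
make_design <- function(n, model = c("I", "II"), seed = NULL) {
  model <- match.arg(model)
  if (n < 2) stop("'n' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  x <- if (model == "I") 5 * u else sin(2 * seq_len(n)) + 1.5 * u
  cbind(`(Intercept)` = 1, x = x)
}

#' Monte Carlo study configuration
#'
#' Bundles the settings shared by [run_estimation_study()] and
#' [run_level_power_study()].  Defaults reproduce the study conditions:
#' true coefficients `(1, 2)`, null `H0: (beta0, beta1) = (1, 2)` with
#' `H = I`, Gibbs NSD errors from `N(0, 0, 1, 16, -0.5)`, levels 0.05 and
#' 0.01, 1000 replicates.
#'
#' @param n sample size per replicate.
#' @param reps number of Monte Carlo replicates (>= 1).
#' @param design `"I"` or `"II"`.
#' @param losses character vector of loss names (subset of ls / lad / huber).
#' @param beta_true true coefficient vector.
#' @param alpha_levels nominal significance levels, each in (0, 1).
#' @param error_cfg an `"nsd_gibbs_config"`.
#' @param omega_n optional local-alternative shift (NULL = null model).
#' @param sigma0 optional error scale fixing the Huber constant
#'   `k = 1.345 sigma0`; NULL estimates it per replicate from preliminary
#'   LS residuals.
#' @param h optional fixed bandwidth; NULL uses [default_bandwidth()].
#' @param seed master seed; per-replicate seeds are drawn from it up front
#'   with `sample.int`, so every replicate has its own reproducible stream.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n = 1000, reps = 1000, design = "I",
                       losses = c("ls", "lad", "huber"),
                       beta_true = c(1, 2), alpha_levels = c(0.05, 0.01),
                       error_cfg = nsd_gibbs_config(), omega_n = NULL,
                       sigma0 = NULL, h = NULL, seed = 1) {
  if (reps < 1) stop("'reps' must be >= 1")
  if (any(alpha_levels <= 0 | alpha_levels >= 1))
    stop("all 'alpha_levels' must lie in (0, 1)")
  losses <- match.arg(losses, c("ls", "lad", "huber"), several.ok = TRUE)
  structure(list(n = n, reps = reps, design = match.arg(design, c("I", "II")),
                 losses = losses, beta_true = beta_true,
                 alpha_levels = alpha_levels, error_cfg = error_cfg,
                 omega_n = omega_n, sigma0 = sigma0, h = h,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-replicate seed streams from the master seed
replicate_seeds <- function(master, reps) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, reps)
}

make_loss_for <- function(name, X, y, sigma0) {
  if (name == "huber")
    make_loss("huber", huber_k = resolve_huber_k(X, y, sigma0)$k)
  else make_loss(name)
}

#' Monte Carlo study of the M-estimators under the null
#'
#' For each replicate: simulate a fresh design and NSD error vector, form
#' `y = X beta_true + e`, fit each requested loss unrestricted, and record
#' the coefficient estimates and the nuisance estimates
#' `sigma2_hat` and `lambda_hat`.  Reports per-loss Monte Carlo means and
#' standard errors (the Table-1-style summary).
#'
#' @param cfg a [sim_config()]; `omega_n` must be NULL.
#' @return a `"sim_report"`: data.frame with one row per loss and columns
#'   `beta0_mean`, `beta1_mean`, `sigma2_mean`, `lambda_mean` plus `_se`
#'   companions, with the configuration in attributes.
#' @export
run_estimation_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$omega_n)) stop("estimation study runs under the null model")
  seeds <- replicate_seeds(cfg$seed, cfg$reps)
  p <- length(cfg$beta_true)
  acc <- lapply(cfg$losses, function(l)
    list(beta = matrix(NA_real_, cfg$reps, p), sigma2 = numeric(cfg$reps),
         lambda = numeric(cfg$reps)))
  names(acc) <- cfg$losses
  for (r in seq_len(cfg$reps)) {
    set.seed(seeds[r])
    X <- make_design(cfg$n, cfg$design)
    e <- gibbs_nsd_errors(cfg$n, cfg$error_cfg)
    y <- drop(X %*% cfg$beta_true) + e
    lev <- leverage_max(X)
    h <- if (is.null(cfg$h)) default_bandwidth(lev$d_n, cfg$n) else cfg$h
    for (l in cfg$losses) {
      loss <- make_loss_for(l, X, y, cfg$sigma0)
      fit <- m_est(x = X, y = y, loss = loss)
      acc[[l]]$beta[r, ] <- stats::coef(fit)
      acc[[l]]$sigma2[r] <- estimate_sigma2(fit$residuals, loss)
      acc[[l]]$lambda[r] <- estimate_lambda(fit$residuals, loss, h)
    }
  }
  rows <- lapply(cfg$losses, function(l) {
    a <- acc[[l]]
    data.frame(loss = l, n = cfg$n, design = cfg$design, reps = cfg$reps,
               beta0_mean = mean(a$beta[, 1]),
               beta0_se = stats::sd(a$beta[, 1]) / sqrt(cfg$reps),
               beta1_mean = mean(a$beta[, 2]),
               beta1_se = stats::sd(a$beta[, 2]) / sqrt(cfg$reps),
               sigma2_mean = mean(a$sigma2),
               sigma2_se = stats::sd(a$sigma2) / sqrt(cfg$reps),
               lambda_mean = mean(a$lambda),
               lambda_se = stats::sd(a$lambda) / sqrt(cfg$reps))
  })
  report <- do.call(rbind, rows)
  attr(report, "config") <- cfg
  class(report) <- c("sim_report", "data.frame")
  report
}

#' Monte Carlo size and power of the M-test
#'
#' For each replicate: simulate data under `beta_true + omega_n` (the null
#' model when `omega_n` is NULL or zero), run the M-test of
#' `H0: beta = beta_true` (H = I, b = beta_true) for each loss, and record
#' rejections at every nominal level.  Reports per-(loss, alpha) empirical
#' rejection rates with Monte Carlo standard errors
#' `sqrt(rate (1 - rate) / reps)` (the Table-2-style summary); under a
#' nonzero `omega_n` the noncentral chi-square theoretical power is attached
#' for comparison.  Replicates in which the lambda estimate is nonpositive
#' (test undefined) are counted in `n_lambda_invalid` and excluded from the
#' rates.
#'
#' @param cfg a [sim_config()].
#' @return a `"sim_report"` data.frame with columns `loss`, `alpha`,
#'   `rejection_rate`, `mc_se`, `power_theoretical` (NA under the null),
#'   `n_lambda_invalid`.
#' @export
run_level_power_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- replicate_seeds(cfg$seed, cfg$reps)
  p <- length(cfg$beta_true)
  hyp <- linear_hypothesis(diag(p), cfg$beta_true)
  omega <- if (is.null(cfg$omega_n)) rep(0, p) else cfg$omega_n
  beta_sim <- cfg$beta_true + omega
  rej <- array(0L, dim = c(length(cfg$losses), length(cfg$alpha_levels),
                           cfg$reps),
               dimnames = list(cfg$losses, NULL, NULL))
  bad <- stats::setNames(integer(length(cfg$losses)), cfg$losses)
  valid <- matrix(TRUE, length(cfg$losses), cfg$reps,
                  dimnames = list(cfg$losses, NULL))
  v_n_acc <- stats::setNames(numeric(length(cfg$losses)), cfg$losses)
  for (r in seq_len(cfg$reps)) {
    set.seed(seeds[r])
    X <- make_design(cfg$n, cfg$design)
    e <- gibbs_nsd_errors(cfg$n, cfg$error_cfg)
    y <- drop(X %*% beta_sim) + e
    for (l in cfg$losses) {
      loss <- make_loss_for(l, X, y, cfg$sigma0)
      tst <- tryCatch(
        m_test(x = X, y = y, loss = loss, hypothesis = hyp,
               alpha = cfg$alpha_levels[1], h = cfg$h,
               omega_n = if (any(omega != 0)) omega else NULL),
        error = function(e2) NULL)
      if (is.null(tst)) { bad[l] <- bad[l] + 1L; valid[l, r] <- FALSE; next }
      for (j in seq_along(cfg$alpha_levels)) {
        crit <- rejection_region(cfg$alpha_levels[j], tst$df, tst$region)
        rej[l, j, r] <- as.integer(tst$statistic < crit$lower_crit ||
                                     tst$statistic > crit$upper_crit)
      }
      if (any(omega != 0)) v_n_acc[l] <- v_n_acc[l] + tst$noncentrality
    }
  }
  rows <- list()
  for (l in cfg$losses) {
    nv <- sum(valid[l, ])
    for (j in seq_along(cfg$alpha_levels)) {
      rate <- if (nv > 0) sum(rej[l, j, valid[l, ]]) / nv else NA_real_
      pw <- NA_real_
      if (any(omega != 0) && nv > 0) {
        crit <- rejection_region(cfg$alpha_levels[j], p, "two_sided_equal_tail")
        pw <- chisq_region_power(v_n_acc[l] / nv, p, crit,
                                 "two_sided_equal_tail")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        loss = l, n = cfg$n, design = cfg$design, reps = cfg$reps,
        alpha = cfg$alpha_levels[j], rejection_rate = rate,
        mc_se = sqrt(rate * (1 - rate) / max(nv, 1)),
        power_theoretical = pw, n_lambda_invalid = bad[[l]])
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "config") <- cfg
  class(report) <- c("sim_report", "data.frame")
  report
}

#' @export
print.sim_report <- function(x, digits = 4, ...) {
  cfg <- attr(x, "config")
  cat("Monte Carlo report: n = ", cfg$n, ", design ", cfg$design,
      ", reps = ", cfg$reps, ", seed = ", cfg$seed, "\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
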