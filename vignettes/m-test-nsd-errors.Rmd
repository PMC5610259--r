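---
title: "Robust M-tests for linear models with negatively superadditive dependent errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust M-tests for linear models with NSD errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsdmtest)
```

## The model and the testing problem

`nsdmtest` is concerned with the linear regression model

$$ y_t = x_t^\top \beta + e_t, \qquad t = 1, \dots, n, $$

when the error sequence $\{e_t\}$ is *negatively superadditive dependent*
(NSD): the expectation of any superadditive function of the errors is
dominated by its value under independent copies with the same marginals.
NSD strictly contains the better-known negatively associated (NA) class and
covers many multivariate models with built-in negative feedback — allocation
of a fixed total across components, sampling without replacement,
negatively correlated measurement channels.  Classical least-squares
inference is doubly fragile here: it is sensitive to outliers, and its
F-calibration presumes independent errors.

The package tests the linear hypothesis

$$ H_0:\; H^\top(\beta - b) = 0 \quad\text{vs.}\quad H_1:\; H^\top(\beta - b) \neq 0, $$

with $H$ a known $p \times q$ matrix of rank $q$ and $b$ a known $p$-vector,
using the **M-criterion**

$$ M_n \;=\; \min_{H^\top(\beta - b) = 0} \sum_t \rho(y_t - x_t^\top\beta)
        \;-\; \min_{\beta} \sum_t \rho(y_t - x_t^\top\beta), $$

for a convex loss $\rho$ with non-decreasing score $\psi$ (a selection
between the one-sided derivatives of $\rho$).  $M_n \ge 0$ measures how much
worse the best fit satisfying the null is than the best unconstrained fit.
Under regularity conditions on the design (maximum leverage
$d_n = \max_t x_t^\top S_n^{-1} x_t = O(1/n)$, $S_n = \sum_t x_t x_t^\top$)
and on the score (a positive derivative $\lambda$ of
$G(u) = E\,\psi(e + u)$ at zero, finite $\sigma^2 = E\,\psi^2(e)$,
summable score covariances), the calibrated statistic

$$ T_n \;=\; \frac{2\hat\lambda_n}{\hat\sigma_n^2}\, M_n $$

is asymptotically chi-square, and noncentral chi-square with noncentrality
$v(n) = \lambda^2 \sigma^{-2} \lVert H_n^\top S_n^{1/2}\omega_n \rVert^2$
under drifting local alternatives $H^\top(\beta - b) = H^\top \omega_n$ with
$\lVert S_n^{1/2}\omega_n\rVert = O(1)$, where
$H_n = S_n^{-1/2} H (H^\top S_n^{-1} H)^{-1/2}$.

### Degrees of freedom

The limiting statistic is the squared norm of the $q$-dimensional projected
score $H_n^\top \sum_t S_n^{-1/2} x_t\, \psi(e_t)$, so the package uses
$\mathrm{df} = q = \operatorname{rank}(H)$.  (Statements of the limit
sometimes quote $p$ degrees of freedom; the two coincide in the fully
pinned case $q = p$, which is also the case exercised by the Monte Carlo
study below.  The `df` field of every result makes the choice visible.)

### The rejection region

The test is calibrated by the *equal-tail* chi-square region: reject when
$T_n$ falls below the $\alpha/2$ quantile or above the $1 - \alpha/2$
quantile of $\chi^2_q$.  Both tails are used because an abnormally small
$M_n$ is also evidence against the model assumptions under this
calibration.  A conventional `upper` mode (reject iff
$T_n > \chi^2_q(1-\alpha)$) is available via the `region` argument.
P-values mirror the region: $2\min(F(T_n), 1 - F(T_n))$ for the equal-tail
mode.

## Losses and solvers

Three built-in losses cover the standard M-estimation families, plus
user-supplied convex losses:

| loss | $\rho(x)$ | $\psi(x)$ | solver |
|------|-----------|-----------|--------|
| `ls` | $x^2/2$ | $x$ | QR / normal equations (exact) |
| `lad` | $\lvert x\rvert$ | $\operatorname{sign}(x)$, $\psi(0)=0$ | smoothed IRLS + vertex polish |
| `huber` | $x^2/2$ for $\lvert x\rvert \le k$, else $k\lvert x\rvert - k^2/2$ | clipped identity | IRLS, LS start |
| custom | user | user | BFGS with analytic gradient |

Numerical choices worth knowing:

* **LAD.** An LAD optimum can always be chosen to interpolate $p$
  observations (a basic solution of the equivalent linear program).  The
  solver first runs iteratively reweighted least squares with Lawson
  weights $1/\max(|r_i|, 10^{-8})$, then *polishes* the solution by exact
  interpolation of the most promising $p$-subsets among the observations
  with the smallest absolute residuals, iterating until no subset improves
  the objective.  The polish adopts a vertex even at objective ties, so the
  returned fit has at least $p$ exactly-zero residuals (they are snapped to
  zero, since interpolation makes them zero by construction).  When several
  vertices tie, the `nonunique` flag is set; the objective value — the only
  input to $M_n$ — is unique regardless.
* **Huber.** IRLS with weights $\psi(r)/r$, relative-change tolerance
  $10^{-10}$, at most 200 iterations, least-squares start.
  Non-convergence is flagged on the fit object and warned about, never
  silent.
* **Huber tuning constant.** $k = 1.345\,\sigma_0$.  The error scale
  $\sigma_0$ is not an input of the theory, so by default it is estimated
  robustly as $\mathrm{MAD}/0.6745$ of preliminary LS residuals; a known
  scale can be fixed via `sigma0` (the simulation study below uses
  $\sigma_0 = \sqrt{13}$, the true stationary error scale, when a fixed
  regime is wanted).
* **LAD kink convention.** $\psi(0) = 0$, the midpoint of the subgradient
  $[-1, 1]$.  A pleasant consequence: the variance estimator for LAD equals
  $(n - z)/n$ with $z$ the number of exactly-zero residuals, hence exactly
  $(n - p)/n$ at a basic solution.
* **Restricted fits** use the null-space reparameterization
  $\beta = b + K\gamma$, with $K$ an orthonormal basis of
  $\operatorname{null}(H^\top)$ from the full QR of $H$ (fixed sign
  convention, hence deterministic).  The restricted problem is an
  unrestricted fit of $y - Xb$ on $XK$; for $q = p$ the fit is $\beta = b$
  with no optimization.  Rank-deficient designs and $n \le p$ are hard
  errors.

## Nuisance estimation and the bandwidth

$\sigma^2$ and $\lambda$ are estimated from the *unrestricted* residuals
(a switch allows restricted residuals for sensitivity analysis):

$$ \hat\sigma_n^2 = n^{-1}\sum_t \psi^2(r_t), \qquad
   \hat\lambda_n = (2nh)^{-1}\sum_t \{\psi(r_t + h) - \psi(r_t - h)\}. $$

For the identity score $\hat\lambda_n = 1$ analytically, for any bandwidth
and any residuals, and the statistic collapses to the familiar
$\Delta\mathrm{RSS} / \hat\sigma^2$.  For kinked scores the bandwidth must
satisfy $h_n \to 0$, $h_n/\sqrt{d_n} \to \infty$ and
$\liminf n h_n^2 > 0$.  The default

$$ h = d_n^{1/4} $$

satisfies all three along any design with $d_n = O(1/n)$ and requires no
tuning input; `default_bandwidth()` additionally checks the finite-sample
surrogates $h/\sqrt{d_n} \ge 1$ and $n h^2 \ge 1$ for the design at hand
and warns when they fail.  A nonpositive $\hat\lambda_n$ (possible for a
score that is flat around all residuals) makes the statistic undefined and
raises an error rather than returning a misleading result.

## The NSD error generator

The error model of the simulation study is $e_t = Y_t + Z_t$ where
$(Y, Z) \sim N(\mu_1, \mu_2, \sigma_1^2, \sigma_2^2, \rho_0)$ with
$\rho_0 < 0$; negatively correlated Gaussian pairs combined this way form
an NSD sequence.  `gibbs_nsd_errors()` realizes the pair sequence by a
systematic-scan Gibbs chain on the bivariate normal —
$Y_t \mid Z_{t-1}$, then $Z_t \mid Y_t$ — initialized at the mean and with
a burn-in of 1000 scans (defaults; moments are stable to well under 1%
between burn-ins of $10^3$ and $10^4$).  Under the default configuration
$N(0, 0, 1, 16, -0.5)$ the stationary error variance is

$$ \operatorname{Var}(e) = \sigma_1^2 + \sigma_2^2 + 2\rho_0\sigma_1\sigma_2
   = 1 + 16 - 4 = 13, $$

which is also $\sigma^2$ for the LS score — a closed-form anchor
(`nsd_error_variance()`) that the estimators can be checked against.  The
general weights $e_t = a Y_t + b Z_t$ are exposed in the configuration but
default to $a = b = 1$.

Two caveats the generator makes explicit rather than hiding:

* The Gibbs *chain* induces serial dependence across $t$ whose lag-1
  autocovariance is not negative for all parameter choices; the chain is
  the literal simulation device, not a certificate of NSD across time.
  For property tests that need a provably NSD (indeed NA) vector,
  `gaussian_na_errors()` draws from $N(0, \Sigma)$ with
  $\Sigma = \tau^2 I - c\,(J - I)$: every pairwise covariance is exactly
  $-c < 0$, and a Gaussian vector with nonpositive correlations is NA,
  hence NSD.
* What passing Monte Carlo tests under this generator shows is calibration
  under *this* dependence structure — Gaussian-mixture marginals, short
  memory.  Heavy-tailed marginals, long-range dependence or positive
  dependence are outside what the generator emulates.

`dependence_diagnostics()` reports lag autocovariances and an empirical CDF
grid for eyeballing both features.

## The Monte Carlo harness

`run_estimation_study()` (coefficient and nuisance recovery under the
null) and `run_level_power_study()` (empirical size, and power under a
shift $\omega_n$) reproduce the study design: model
$y_t = \beta_0 + \beta_1 x_t + e_t$ with $(\beta_0, \beta_1) = (1, 2)$,
designs $x_t = 5u_t$ (I) or $x_t = \sin 2t + 1.5 u_t$ (II) with standard
uniform $u_t$, null $H_0: (\beta_0, \beta_1) = (1, 2)$ tested with
$H = I_2$, levels 0.05 and 0.01, and 1000 replicates of size
$n \in \{100, 500, 1000\}$.  Each replicate draws a fresh design and a
fresh Gibbs chain from its own seed; the per-replicate seeds are drawn up
front from the master seed by `sample.int`, so a study is reproducible from
a single integer and replicates are independent (a single sliced chain
would not give the independent averages the summary presumes).

Reference values under design I at $n = 1000$, to which the test suite and
`scripts/acceptance.R` compare within Monte Carlo tolerance: LS means
$\hat\beta_0 \approx 1.002$, $\hat\beta_1 \approx 1.997$,
$\hat\sigma^2 \approx 12.97$; $\hat\lambda = 1$ (LS),
$\approx 0.233$ (LAD), $\approx 0.822$ (Huber with $\sigma_0=\sqrt{13}$;
the population value is $2\Phi(1.345) - 1 \approx 0.821$);
LAD $\hat\sigma^2 = 0.998 = (n-2)/n$ exactly; empirical levels near the
nominal 0.05 / 0.01 (e.g. $\approx 0.056$ for LS, $\approx 0.048$ for
Huber at $\alpha = 0.05$).  Since the bandwidth, burn-in and random streams
behind such published summaries are never fully specified, all comparisons
are tolerance-banded, not digit-exact.  The problem sizes used by the test
suite (unit tests on $n \le 10^3$ with tens of replicates; the end-to-end
checks at $n = 1000$ with 300–1000 replicates; chain-moment checks at
$n = 10^6$) were chosen to keep every Monte Carlo band at 3–4 standard
errors while the whole suite runs in about a minute.

## A worked example

```{r example}
set.seed(42)
X <- make_design(500, "I")
y <- drop(X %*% c(1, 2)) + gibbs_nsd_errors(500)
fit <- m_est(x = X, y = y, loss = "huber")
coef(fit)

m_test(x = X, y = y, loss = "huber",
       hypothesis = linear_hypothesis(diag(2), c(1, 2)))
```

Power against a local alternative, with its noncentral prediction:

```{r power}
run_level_power_study(sim_config(n = 500, reps = 100, losses = "ls",
                                 omega_n = c(0.25, 0), alpha_levels = 0.05,
                                 seed = 7))
```

## Known limitations

* Asymptotic calibration only: no bootstrap or permutation fallback, so
  very small $n$ with highly kinked losses relies on the chi-square
  approximation.
* One hypothesis per call — no multiplicity handling.
* Convex losses only; redescending scores (Tukey biweight) are outside the
  theory and rejected by the convexity check.
* The LAD solver's vertex polish enumerates $\binom{2p+2}{p}$ candidate
  subsets per pass, which is meant for the low-dimensional regimes the
  asymptotics cover, not for large $p$.
* High-dimensional ($p \ge n$) or penalized estimation is out of scope.
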