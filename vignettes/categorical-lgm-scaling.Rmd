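---
title: "Scaling and estimating latent growth models with categorical indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling and estimating latent growth models with categorical indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catlgm)
```

## The model

`catlgm` works with linear latent growth models (LGMs) for longitudinal
categorical responses. Each observed category is assumed to arise by
thresholding a continuous latent response variable $y^*_{it}$,

$$y^*_{it} = \eta_{0i} + \eta_{1i}\lambda_t + e_{it},$$

with individual intercept $\eta_{0i} = \alpha_{00} + \zeta_{0i}$ and slope
$\eta_{1i} = \alpha_{10} + \zeta_{1i}$, loadings $\lambda_t = t - 1$, growth
factor covariance matrix
$\begin{pmatrix}\psi_{00} & \psi_{10}\\ \psi_{10} & \psi_{11}\end{pmatrix}$
and occasion error variances $\theta_t$. The implied latent moments are

$$\mu^*_t = \alpha_{00} + \alpha_{10}\lambda_t, \qquad
\sigma^*_t = \psi_{00} + 2\lambda_t\psi_{10} + \lambda_t^2\psi_{11} + \theta_t, \qquad
\sigma^*_{tu} = \psi_{00} + (\lambda_t + \lambda_u)\psi_{10} + \lambda_t\lambda_u\psi_{11}.$$

Because the slope contributes $\lambda_t^2\psi_{11}$ and $\theta_t$ typically
grows, the latent variance *changes over time*. This heteroscedasticity is
exactly what makes scale assignment consequential: the latent response
variables have no metric of their own, and the information used to give them
one (the *observed scale references*) differs between ordinal and binary
indicators.

## The observed-scale-reference calculus

At each occasion the latent response variable is first represented on the
z-scale, where its thresholds are the standard-normal quantiles of the
cumulative category proportions (`z_thresholds()`). Constructing a common
longitudinal scale then requires an origin and a unit:

* **Ordinal indicators (3+ categories).** Two thresholds serve as
  references: the first fixes the origin, and the gap to the second fixes
  the unit length $w_t$ (`ordinal_unit_length()`). The unit is therefore
  *independent of the origin's location*.
* **Binary indicators.** Only one threshold exists, so the unit is taken
  from the standard deviation of the observed variable:
  $w_t = \sqrt{1/(p_t(1 - p_t))}$ (`binary_unit_length()`). Note this is the
  reciprocal Bernoulli *standard deviation*, not the reciprocal variance
  $1/(p_t(1-p_t))$ — at a 70% response rate the unit is
  $\sqrt{1/0.21} \approx 2.18$, while the un-rooted quantity would be 4.76.
  The unit is minimal (exactly 2) at $p_t = 0.5$ and grows as the threshold
  moves away from 0: for binary data the unit is a *function of the
  origin*.

Imposing a common unit $w$ (that of the reference occasion, by default the
first) rescales occasion $t$ to standard deviation
$\sqrt{s^*_t} = w_{\mathrm{ref}}/w_t$, conserving $w_t\sqrt{s^*_t} = w$, and
anchoring one threshold at a common value (default 0) gives the means
$\bar y^*_t = \mathrm{anchor} - \sqrt{s^*_t}\,\tau^z_t$. `scale_summary()`
runs the whole chain:

```{r}
centers <- c(-1, 0, 1)  # the same threshold drift, seen two ways
ordinal_p <- t(sapply(centers, function(m) diff(c(0, pnorm(m + c(-0.83, 0.83)), 1))))
binary_p  <- cbind(pnorm(centers), 1 - pnorm(centers))
scale_summary(ordinal_p)
scale_summary(binary_p)
```

With equal inter-threshold gaps the ordinal units are flat, so the
common-scale SDs stay at 1. The binary units are smallest where the
response rate passes 0.5, so $\sqrt{s^*}$ *humps* at the middle occasion —
even though the underlying response-rate change is identical. This
divergence, mechanical and data-independent, is why binary growth models can
misrepresent the population's variance profile while ordinal ones do not.

### Design choices in the calculus

* With more than three categories the unit pair is ambiguous; the package
  uses the **first two thresholds** (matching the origin-plus-next-gap
  anchoring above) and exposes the pair as an argument.
* Anchoring: first threshold at 0, reference occasion 1 with
  $\sqrt{s^*_1} = 1$ — mirroring the delta parameterization with
  $\Delta_1 = 1$ used by the estimator. Only pairwise relations are
  determined by the invariance argument, so *some* anchor is required.
* Degenerate proportions (a category never observed) **raise an error**
  rather than being clipped: downstream the replicate is counted as an
  estimation difficulty, never silently repaired.

## The synthetic-data generator

`simulate_panel()` reproduces the simulation design the package is built to
study. Latent trajectories are drawn directly from the implied multivariate
normal (distributionally equivalent to composing growth factors and errors)
and discretised by invariant thresholds; values exactly at a cut go to the
upper category (a probability-zero tie-break fixed for determinism).

The generator's defaults *are* the study conditions:

* occasion means from the pattern (shift / increase / decrease) and slope
  level (large $\alpha_{10} = 0.40$, small $0.10$), e.g. shift/large means
  $(-0.6, -0.2, 0.2, 0.6)$;
* $\psi_{00} = 0.5$, $\psi_{11} = 0.1$, $\psi_{10} = 0$,
  $\theta = (0.5, 0.6, 0.9, 1.4)$, so the latent variances increase as
  $(1.0, 1.2, 1.8, 2.8)$;
* symmetric thresholds $0$ (binary), $\pm 0.83$ (three categories),
  $(\pm 1.25, 0)$ (four categories);
* sample sizes $N \in \{100, 200, 1000\}$, giving the 54-condition
  factorial of `condition_grid()`.

Seeds are counter-based (`replicate_seed()`): each (condition, replicate)
pair has its own seed below $2^{31}$, so any condition can be re-run or
resumed independently and results do not depend on execution order.

What the generator does *not* emulate: missing data, non-linear growth,
time-varying thresholds, non-normal latent distributions, or clustered
sampling. Passing tests therefore demonstrate correct behaviour under a
correctly specified probit world, not robustness to the violations real
panels bring.

## The estimator

`catlgm()` fits the model in three stages:

1. **Thresholds** (`sample_thresholds()`): probit quantiles of each
   occasion's cumulative proportions.
2. **Polychorics** (`polychoric()`): for each occasion pair, the
   bivariate-normal likelihood of the contingency table is maximised over
   the correlation with stage-1 thresholds held fixed (one-dimensional
   search on $(-0.999, 0.999)$, tolerance $10^{-7}$; estimates against the
   boundary are flagged).
3. **DWLS** (`fit_dwls()`): the stacked statistics $s$ (thresholds, then
   unique correlations) are fitted by minimising
   $(s - \sigma(\theta))^\top W^{-1} (s - \sigma(\theta))$ with
   $W = \mathrm{diag}$ of estimated asymptotic variances.

Under the delta parameterization the free parameters are the invariant
thresholds $\tau_c$, the slope mean $\alpha_{10}$ (the intercept mean is
fixed at 0, the standard identification for categorical growth models, so
$\tau_c$ absorbs the latent origin and the reported $\alpha_{10}$ is
unaffected), the growth-factor covariances, and scale factors $\Delta_t$ for
$t \ge 2$ with $\Delta_1 = 1$. The implied statistics are
$\Delta_t(\tau_c - \alpha_{10}\lambda_t)$ and
$\Delta_t\Delta_u\,\mathrm{cov}_{tu}$; at the solution $\Delta_t$ is the
inverse latent standard deviation, with population value
$\sqrt{\sigma^*_1/\sigma^*_t} = (0.913, 0.745, 0.598)$ for occasions 2–4 in
every study condition.

### Weights

The diagonal weights are estimated asymptotic variances: the probit
delta-method formula $P(1-P)/(N\phi(\tau)^2)$ for thresholds, and inverse
observed information of the stage-2 pairwise likelihood for correlations
(numerical second derivative at the estimate, thresholds fixed — a
consistent estimator that ignores threshold-estimation noise in the
correlation entries). If any entry is non-positive or non-finite the fit
falls back to unit weights with a warning. The mean-and-variance adjustment
that usually accompanies this estimator affects only test statistics, which
the package does not compute; point estimates are pure DWLS.

### Numerical choices

* Quasi-Newton (BFGS) on log scale factors (clamped to $\pm 30$ so line
  searches cannot underflow), with the growth-factor covariances left
  **unconstrained** so improper solutions can occur and be classified
  rather than being hidden by a boundary.
* Relative function tolerance $10^{-10}$, iteration cap 500; a soft
  quadratic penalty keeps implied correlations inside $(-1, 1)$.
* Starts: a moment-based start (stage-1 thresholds; slope from the drift of
  the thresholds; $\Delta$ from the scaling calculus' unit-length ratios,
  which is exact in the ordinal population case) followed by two fixed
  fallback starts; the first converged start is accepted, and a fit is
  `nonconverged` only after all starts fail.
* Status: `improper` means converged with $\hat\psi_{11} < 0$,
  $\hat\psi_{00} < 0$ or a non-positive-semidefinite factor covariance;
  degenerate panels (an empty category) are rejected before fitting.

Fitting the *analytic* population statistics (`population_statistics()`)
recovers the generating parameters to optimizer precision for every study
condition — binary included, since with $\sigma^*_1 = 1$ the population
statistics are exactly reproducible with $\Delta_t = 1/\sqrt{\sigma^*_t}$.
The binary pathology is a finite-sample phenomenon: the weakly identified
binary scale factors make the sampling distribution of
$(\hat\alpha_{10}, \hat\psi_{11}, \hat\Delta_t)$ disperse and skew, which
the Monte Carlo layer reproduces.

## The Monte Carlo driver

`run_condition()` generates, fits and classifies each replicate, then
aggregates relative bias $(\bar{\hat\theta} - \theta)/\theta$ and RMSE
$\sqrt{\overline{(\hat\theta - \theta)^2}}$ for $\alpha_{10}$, $\psi_{11}$
and $\Delta_{2..4}$, with a Monte Carlo standard error next to every RB so
tolerance checks stay principled.

* **Denominator:** RB/RMSE are computed over converged *proper* replicates
  only — the only definition under which conditions with majority
  difficulties can report estimates at all; `include_improper = TRUE` is a
  sensitivity switch. The difficulty rate is the share of attempts that did
  not end in a converged proper solution, with degenerate panels counted
  and reported separately from optimizer failures.
* **Replications:** desk-scale runs use 200 replicates per condition in the
  test suite and 500 in the reproduction script (the full design used
  1,000); at 200 replicates the MC standard error of an ordinal RB on
  $\alpha_{10}$ at $N = 1000$ is about 0.005, comfortably inside the 5%
  band being checked, while the binary cells carry SEs of several
  percentage points — which is why every RB is reported with its MC
  standard error and checks compare at three of them.
* Convergence-difficulty *rates* depend on optimizer internals
  (tolerances, start strategies, improper-solution definitions differ
  across implementations), so only their direction — binary well above
  ordinal in small-slope conditions — is asserted, not their levels.

## Known limitations

Two-stage polychorics (thresholds fixed at stage 1) are assumed; fully
simultaneous estimation would differ slightly at small $N$. Standard errors
of the structural parameters are not computed. The correlation weights omit
threshold-uncertainty terms. None of these affect the scaling calculus,
which is exact arithmetic, and all are documented choices rather than
claims about external software behaviour.
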