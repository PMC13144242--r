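# catlgm

Latent growth models (LGMs) for longitudinal **categorical** responses are
estimated through continuous latent response variables: each observed
category is a thresholded reading of an underlying normal tendency
$y^*_{it} = \eta_{0i} + \eta_{1i}\lambda_t + e_{it}$. Before such a model
can be fitted, every $y^*_t$ must be given a scale, and the information
available for that differs by indicator type: ordinal indicators supply two
thresholds (origin + unit), while binary indicators supply one threshold
plus the observed standard deviation, whose unit length
$w_t = \sqrt{1/(p_t(1-p_t))}$ is tied to the threshold's location. That
difference makes binary LGMs systematically harder to estimate than ordinal
ones, even from identical latent populations.

`catlgm` is for methodologists and applied researchers who want to study —
or check — this scaling behaviour. It provides:

* the **observed-scale-reference calculus**: `z_thresholds()`,
  `ordinal_unit_length()`, `binary_unit_length()`, `common_scale_sds()`,
  `common_scale_means()` and the one-call `scale_summary()`, which turn
  per-occasion category proportions into common-scale latent means and
  standard deviations via the conservation identity
  $w_t\sqrt{s^*_t} = w$;
* a **population model and panel generator**: `growth_spec()`,
  `implied_moments()` ($\mu^*_t = \alpha_{00} + \alpha_{10}\lambda_t$,
  $\sigma^*_t = \psi_{00} + 2\lambda_t\psi_{10} + \lambda_t^2\psi_{11} +
  \theta_t$), `simulate_panel()`, and the 54-condition factorial design in
  `condition_grid()`;
* the **estimator**: `catlgm()` fits the model by probit thresholds →
  pairwise polychoric correlations (`polychoric()`, maximum likelihood with
  fixed thresholds) → diagonally weighted least squares under the delta
  parameterization with $\Delta_1 = 1$ (`fit_dwls()`), returning a classed
  fit with `print`, `summary`, `coef`, `fitted`, `residuals`, `simulate`
  and `plot` methods;
* a **Monte Carlo driver**: `run_condition()` / `run_grid()` classify
  replicates (converged / improper / nonconverged / degenerate) and
  aggregate relative bias and RMSE for $\alpha_{10}$, $\psi_{11}$ and the
  scale factors $\Delta_t$, with `report_tables()` producing
  difficulties-by-condition and per-pattern results tables.

## Worked example

Generate a three-category panel under the large-slope shift condition and
fit it:

```r
library(catlgm)
panel <- simulate_panel(condition_spec("shift", "large"), n = 1000,
                        thresholds = default_thresholds(3), seed = 42,
                        label = "shift/large")
fit <- catlgm(panel)
summary(fit)
#> Categorical latent growth model (DWLS, delta parameterization)
#> call: catlgm(panel = panel)
#>
#> N = 1000  categories = 3  status = converged
#>
#> Estimates:
#>    tau1    tau2 alpha10   psi00   psi10   psi11  delta2  delta3  delta4
#> -0.2336  1.3858  0.3949  0.5669 -0.0397  0.1152  0.9612  0.7256  0.6378
#>
#> Implied latent mean trajectory (origin at occasion 1):
#> [1] 0.0000 0.3949 0.7898 1.1846
#> Implied latent SDs (1 / Delta_t):
#> [1] 1.0000 1.0403 1.3782 1.5680
#>
#> Discrepancy: 1.085  ( 76 function evaluations )
```

The slope mean is recovered (0.3949 vs. the generating 0.40), and the
estimated scale factors track the population values
$\Delta_t = \sqrt{\sigma^*_1/\sigma^*_t} = (0.913, 0.745, 0.598)$: the
implied latent SDs rise over time as designed. Reading: `tau1`/`tau2` are
the invariant thresholds (they absorb the latent origin, since the
intercept mean is fixed at 0 for identification), `alpha10`/`psi11` the
slope mean and variance, `delta2..4` the inverse latent SDs at occasions
2–4.

A condition-level Monte Carlo run:

```r
r <- run_condition(condition("decrease", "large", 2, 1000, id = 16),
                   reps = 200, base_seed = 1)
r
#> Condition: decrease pattern, large slope, 2 categories, N = 1000
#> 200 replicates: 197 converged, 3 improper, 0 nonconverged, 0 degenerate
#> estimation difficulties: 1.5%
#>            alpha10 psi11 delta2 delta3 delta4
#> true         0.400 0.100  0.913  0.745  0.598
#> RB           0.084 0.628  0.008  0.022  0.033
#> RB (MC SE)   0.034 0.217  0.017  0.021  0.023
#> RMSE         0.193 0.310  0.219  0.220  0.196
```

Even at $N = 1000$ the binary fit keeps a moderate slope-mean bias
(RB 8.4%) under the decrease pattern, while ordinal fits of the same latent
population are essentially unbiased — the package's central phenomenon.

The scaling calculus alone (no fitting) shows why:

```r
centers <- c(-1, 0, 1)                       # same response-rate drift
binary_p <- cbind(pnorm(centers), 1 - pnorm(centers))
scale_summary(binary_p)$sds
#> [1] 1.000000 1.368535 1.000000   # binary common-scale SDs hump in the middle
```

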