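test_that("sample thresholds are probit quantiles of the cumulative counts", {
  panel <- cbind(rep(0:1, times = c(30, 70)), rep(0:1, times = c(50, 50)))
  tau <- sample_thresholds(panel, categories = 2)
  expect_equal(tau[[1]], qnorm(0.30))
  expect_equal(round(tau[[1]], 2), -0.52)
  expect_equal(tau[[2]], 0)

  empty <- cbind(rep(0L, 100), rep(0:1, 50))
  expect_error(sample_thresholds(empty, categories = 2),
               class = "catlgm_degenerate")
})

test_that("independence tables give a zero polychoric correlation", {
  tab <- outer(c(200, 300), c(240, 260)) / 500  # exact product of margins
  rho <- polychoric(tab)
  expect_lt(abs(as.numeric(rho)), 1e-6)
  expect_false(attr(rho, "boundary"))
})

test_that("the tetrachoric MLE recovers a known latent correlation", {
  set.seed(21)
  y <- MASS::mvrnorm(1e5, mu = c(0, 0),
                     Sigma = matrix(c(1, 0.5, 0.5, 1), 2))
  panel <- categorize(y, 0)
  rho <- polychoric(panel[, 1], panel[, 2])
  expect_lt(abs(as.numeric(rho) - 0.5), 0.01)
})

test_that("the polychoric correlation is symmetric in its arguments", {
  set.seed(22)
  y <- MASS::mvrnorm(2000, mu = c(0, 0.3),
                     Sigma = matrix(c(1, 0.4, 0.4, 1), 2))
  x1 <- categorize(y[, 1], c(-0.8, 0.6))
  x2 <- categorize(y[, 2], c(-0.8, 0.6))
  r12 <- as.numeric(polychoric(x1, x2))
  r21 <- as.numeric(polychoric(x2, x1))
  expect_equal(r12, r21, tolerance = 1e-8)
})

test_that("threshold weights follow the probit delta method and scale as 1/N", {
  # balanced two-occasion binary panel built from exact counts
  panel <- cbind(rep(0:1, each = 200), rep(rep(0:1, each = 100), 2))
  m <- sample_moments(panel, categories = 2)
  expect_equal(m$acov[1], 0.25 / (400 * dnorm(0)^2))
  expect_equal(m$acov[1], 1.5708 / 400, tolerance = 1e-4)
  expect_true(all(m$acov > 0))

  m2 <- sample_moments(rbind(panel, panel), categories = 2)
  expect_equal(m2$acov, m$acov / 2, tolerance = 1e-6)
})

test_that("the probit-quantile variance matches its sampling distribution", {
  set.seed(23)
  tauhats <- replicate(2000, qnorm(mean(rbinom(500, 1, 0.5))))
  expect_equal(var(tauhats), 0.25 / (500 * dnorm(0)^2), tolerance = 0.15)
})

test_that("implied statistics reproduce the delta-parameterized mapping", {
  # generating values of the large-slope shift condition, thresholds at 0;
  # the model's invariant threshold absorbs the -0.6 intercept mean
  imp <- implied_statistics(tau = 0.6, alpha10 = 0.4, psi00 = 0.5,
                            psi11 = 0.1, psi10 = 0,
                            delta = 1 / sqrt(c(1.2, 1.8, 2.8)),
                            loadings = 0:3)
  expect_equal(round(imp$thresholds[, 1], 3), c(0.600, 0.183, -0.149, -0.359))
  expect_equal(imp$rho, t(imp$rho))
  expect_equal(imp$rho, cov2cor(implied_moments(condition_spec("shift", "large"))$cov),
               tolerance = 1e-12)

  # no-growth degenerate case: flat thresholds, compound-symmetric correlations
  flat <- implied_statistics(tau = c(-0.5, 0.5), alpha10 = 0, psi00 = 0.4,
                             psi11 = 0, psi10 = 0, delta = rep(1, 3),
                             loadings = 0:3)
  expect_equal(max(apply(flat$thresholds, 2, function(col) diff(range(col)))), 0)
  off <- flat$rho[upper.tri(flat$rho)]
  expect_equal(max(off) - min(off), 0)
})

test_that("population statistics identify the binary model exactly", {
  spec <- condition_spec("shift", "large")
  f <- fit_dwls(population_statistics(spec, default_thresholds(2)))
  expect_equal(f$status, "converged")
  est <- f$estimates
  expect_equal(unname(est["tau1"]), 0.6, tolerance = 1e-4)
  expect_equal(unname(est["alpha10"]), 0.4, tolerance = 1e-4)
  expect_equal(unname(est["psi11"]), 0.1, tolerance = 1e-4)
  expect_equal(unname(est[c("delta2", "delta3", "delta4")]),
               sqrt(1 / c(1.2, 1.8, 2.8)), tolerance = 1e-4)
  expect_lt(f$discrepancy, 1e-8)
})

test_that("a large ordinal sample recovers the slope mean", {
  panel <- simulate_panel(condition_spec("shift", "large"), 5000,
                          default_thresholds(4), seed = 101)
  fit <- catlgm(panel)
  expect_equal(fit$status, "converged")
  expect_lt(abs(coef(fit)[["alpha10"]] - 0.4), 0.03)
  expect_lt(abs(coef(fit)[["psi11"]] - 0.1), 0.03)
})

test_that("the fit is invariant to subject order and mirrors under reversal", {
  panel <- simulate_panel(condition_spec("shift", "large"), 1000,
                          default_thresholds(2), seed = 55)
  fit <- catlgm(panel)

  set.seed(66)
  perm <- unclass(panel)[sample(nrow(panel)), ]
  fit_perm <- catlgm(perm, categories = 2)
  expect_equal(coef(fit), coef(fit_perm))

  rev <- 1L - unclass(panel)
  fit_rev <- catlgm(rev, categories = 2)
  expect_equal(coef(fit_rev)[["alpha10"]], -coef(fit)[["alpha10"]],
               tolerance = 1e-3)
  expect_equal(coef(fit_rev)[["tau1"]], -coef(fit)[["tau1"]],
               tolerance = 1e-3)
  expect_equal(coef(fit_rev)[["delta3"]], coef(fit)[["delta3"]],
               tolerance = 1e-3)
})

test_that("fit methods expose implied statistics, residuals and simulation", {
  panel <- simulate_panel(condition_spec("shift", "large"), 2000,
                          default_thresholds(3), seed = 77)
  fit <- catlgm(panel)
  expect_s3_class(fit, "catlgm")
  r <- residuals(fit)
  expect_length(r, 8 + 6)  # 2 thresholds x 4 occasions + 6 correlations
  expect_lt(max(abs(r)), 0.2)
  expect_equal(fit$discrepancy, sum(r^2 / fit$moments$acov),
               tolerance = 1e-6)
  sim <- simulate(fit, seed = 3, n = 500)
  expect_equal(dim(sim), c(500, 4))
  expect_true(all(sim %in% 0:2))
  s <- summary(fit)
  expect_equal(s$status, "converged")
  expect_length(s$latent_sd, 4)
})
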