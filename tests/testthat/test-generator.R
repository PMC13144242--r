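test_that("implied moments follow the linear growth algebra", {
  spec <- condition_spec("shift", "large")
  m <- implied_moments(spec)
  expect_equal(m$mean, c(-0.6, -0.2, 0.2, 0.6))
  expect_equal(diag(m$cov), c(1.0, 1.2, 1.8, 2.8))
  expect_equal(m$cov[1, 2], 0.5)
  expect_equal(m$cov[3, 4], 0.5 + 6 * 0.1)
  expect_equal(m$cov, t(m$cov))
})

test_that("condition labels map to the design means", {
  expect_equal(implied_moments(condition_spec("increase", "small"))$mean,
               c(-0.3, -0.2, -0.1, 0))
  expect_equal(implied_moments(condition_spec("decrease", "large"))$mean,
               c(0, 0.4, 0.8, 1.2))
  expect_equal(implied_moments(condition_spec("shift", "large"))$mean[4], 0.6)
  expect_error(condition_spec("wiggle", "large"))
})

test_that("the factorial grid holds 54 distinct conditions with distinct seeds", {
  g <- condition_grid()
  expect_equal(nrow(g), 54)
  expect_equal(anyDuplicated(g[, -1]), 0)
  hit <- g[g$pattern == "shift" & g$slope == "large" &
             g$categories == 2 & g$n == 100, ]
  expect_equal(nrow(hit), 1)
  seeds <- replicate_seed(7, g$id, 1)
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds > 0) && all(seeds < 2^31))
  expect_equal(anyDuplicated(replicate_seed(7, 1, 1:1000)), 0)
})

test_that("invalid growth specifications are rejected", {
  expect_error(growth_spec(0, 0.4, psi00 = 0.1, psi11 = 0.1, psi10 = 0.5),
               "semidefinite")
  expect_error(growth_spec(0, 0.4, theta = c(0.5, -0.1)))
})

test_that("categorisation counts thresholds at or below the value", {
  expect_equal(categorize(c(-5, 0.3), 0), c(0L, 1L))
  expect_equal(categorize(c(-1.25, 0, 1.25), c(-1.25, 0, 1.25)),
               c(1L, 2L, 3L))  # a value at a cut goes up
  expect_equal(categorize(-5, c(-1.25, 0, 1.25)), 0L)
  expect_error(categorize(0, c(1, 0)), "increasing")
})

test_that("the same seed reproduces panels exactly", {
  spec <- condition_spec("shift", "large")
  p1 <- simulate_panel(spec, 50, default_thresholds(3), seed = 42)
  p2 <- simulate_panel(spec, 50, default_thresholds(3), seed = 42)
  expect_identical(p1, p2)
  p3 <- simulate_panel(spec, 50, default_thresholds(3), seed = 43)
  expect_false(identical(p1, p3))
})

test_that("large samples match the closed-form moments and category rates", {
  spec <- condition_spec("shift", "large")
  n <- 1e5
  y <- simulate_latent(spec, n, seed = 9)
  m <- implied_moments(spec)
  se_mean <- sqrt(diag(m$cov) / n)
  expect_true(all(abs(colMeans(y) - m$mean) < 3 * se_mean))
  S <- cov(y)
  se_cov <- sqrt((outer(diag(m$cov), diag(m$cov)) + m$cov^2) / n)
  expect_true(all(abs(S - m$cov) < 3 * se_cov))

  # binary split at occasion 1: P(category 1) = P(y* >= 0) = pnorm(-0.6)
  p1 <- mean(categorize(y[, 1], 0))
  target <- pnorm(-0.6)
  expect_lt(abs(p1 - target), 3 * sqrt(target * (1 - target) / n))

  # three-category proportions at occasion 3 against the normal rectangle
  thr <- default_thresholds(3)
  pr <- panel_proportions(categorize(y, thr), categories = 3)
  expected <- diff(c(0, pnorm((thr - m$mean[3]) / sqrt(m$cov[3, 3])), 1))
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(pr[3, ] - expected) < 3 * se))
})

test_that("panel files round-trip through the delimited format", {
  p <- simulate_panel(condition_spec("decrease", "small"), 30,
                      default_thresholds(4), seed = 5,
                      label = "decrease/small")
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  q <- read_panel(f)
  expect_equal(as.vector(p), as.vector(q))
  expect_equal(dim(p), dim(q))
  expect_equal(colnames(q), paste0("t", 1:4))
  expect_identical(attr(q, "categories"), 4L)
  expect_identical(attr(q, "label"), "decrease/small")
})
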