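test_that("relative bias and RMSE follow their definitions", {
  expect_equal(relative_bias(rep(0.44, 10), 0.40), 0.10)
  expect_equal(relative_bias(c(0.3, 0.5), 0.4), 0)
  expect_equal(relative_bias(c(0.5, 0.7), 0.5), 0.2)
  expect_error(relative_bias(c(0.1, 0.2), 0), "undefined")
  expect_error(relative_bias(numeric(0), 1))

  expect_equal(rmse(rep(0.4, 5), 0.4), 0)
  expect_equal(rmse(c(0.3, 0.5), 0.4), 0.1)
  set.seed(4)
  for (i in 1:20) {
    est <- rnorm(30, 1, 0.3)
    true <- runif(1, 0.5, 2)
    expect_gte(rmse(est, true) + 1e-12, abs(mean(est) - true))
  }
})

test_that("replicate aggregation classifies outcomes and computes rates", {
  df <- data.frame(
    status = c(rep("converged", 7), "improper", "nonconverged", "degenerate"),
    alpha10 = c(0.41, 0.42, 0.43, 0.44, 0.45, 0.46, 0.47, 9, NA, NA)
  )
  agg <- catlgm:::summarize_replicates(df, c(alpha10 = 0.4))
  expect_equal(agg$counts[["attempted"]], 10)
  expect_equal(sum(agg$counts[-1]), agg$counts[["attempted"]])
  expect_equal(agg$difficulty, 30)
  expect_equal(agg$rb[["alpha10"]], 0.1)  # converged replicates only
  expect_equal(agg$n_used, 7)

  agg2 <- catlgm:::summarize_replicates(df, c(alpha10 = 0.4),
                                        include_improper = TRUE)
  expect_equal(agg2$n_used, 8)
  expect_gt(agg2$rb[["alpha10"]], agg$rb[["alpha10"]])

  # doubling the replicate pool shrinks the Monte Carlo SE by sqrt(2)
  agg4 <- catlgm:::summarize_replicates(rbind(df, df), c(alpha10 = 0.4))
  expect_equal(agg$rb_se[["alpha10"]] / agg4$rb_se[["alpha10"]], sqrt(2),
               tolerance = 0.05)
})

test_that("condition runs are deterministic and resumable", {
  cond <- condition("shift", "large", 3, 200, id = 5)
  r1 <- run_condition(cond, reps = 5, base_seed = 11)
  r2 <- run_condition(cond, reps = 5, base_seed = 11)
  expect_equal(r1$results, r2$results)
  expect_equal(r1$rb, r2$rb)
  expect_equal(sum(r1$counts[-1]), r1$counts[["attempted"]])

  r3 <- run_condition(cond, reps = 5, base_seed = 12)
  expect_false(identical(r1$results$alpha10, r3$results$alpha10))

  cache <- withr::local_tempfile(fileext = ".csv")
  r4 <- run_condition(cond, reps = 5, base_seed = 11, cache_file = cache)
  expect_true(file.exists(cache))
  before <- file.mtime(cache)
  r5 <- run_condition(cond, reps = 5, base_seed = 11, cache_file = cache)
  expect_equal(file.mtime(cache), before)  # cache reused, fits not re-run
  expect_equal(r4$rb, r5$rb)
  expect_equal(r4$rb, r1$rb)
})

test_that("report tables cover the grid with explicit gap markers", {
  g <- condition_grid()
  reports <- list(
    run_condition(grid_condition(g, "shift", "large", 3, 100), reps = 3,
                  base_seed = 2),
    run_condition(grid_condition(g, "shift", "large", 2, 100), reps = 3,
                  base_seed = 2)
  )
  tabs <- report_tables(reports)
  expect_equal(nrow(tabs$difficulties), 18)  # pattern x slope x N
  expect_equal(sum(!is.na(tabs$difficulties$cat3)), 1)
  expect_equal(sum(!is.na(tabs$difficulties$cat2)), 1)
  expect_true(all(is.na(tabs$difficulties$cat4)))

  expect_equal(nrow(tabs$estimates), 54 * 5)  # alpha10, psi11, delta2..4
  filled <- !is.na(tabs$estimates$rb)
  expect_equal(sum(filled), 2 * 5)

  wide <- format_pattern_table(tabs$estimates, "shift")
  expect_equal(nrow(wide), 3 * 5)  # N x parameter
  expect_true(all(c("large3_rb", "small4_rmse") %in% colnames(wide)))

  # cells survive a 3-decimal write/read round trip
  f <- withr::local_tempfile(fileext = ".csv")
  est <- tabs$estimates
  est[c("rb", "rb_se", "rmse")] <- round(est[c("rb", "rb_se", "rmse")], 3)
  write.csv(est, f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$rb, est$rb)
  expect_equal(back$rmse, est$rmse)
})
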