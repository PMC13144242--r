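#' Relative bias of a set of estimates
#'
#' `(mean(estimates) - true) / true`: the proportional difference between the
#' average estimate and the generating value. Values closer to zero indicate
#' more accurate estimation; below 0.05 is conventionally read as trivial
#' bias, 0.05-0.10 as moderate and above 0.10 as substantial.
#'
#' @param estimates Non-empty numeric vector of estimates.
#' @param true Non-zero generating value.
#' @return Relative bias on the proportion scale (0.062, not 6.2).
#' @examples
#' relative_bias(c(0.5, 0.7), 0.5)  # 0.2
#' @export
relative_bias <- function(estimates, true) {
  if (length(estimates) == 0L) stop("`estimates` must be non-empty")
  if (!is.numeric(true) || true == 0) {
    stop("relative bias is undefined for a true value of 0")
  }
  (mean(estimates) - true) / true
}

#' Root mean square error of a set of estimates
#'
#' `sqrt(mean((estimates - true)^2))`: variability of the estimates around
#' the generating value across replications.
#'
#' @inheritParams relative_bias
#' @param true Generating value (may be zero).
#' @return Non-negative RMSE.
#' @examples
#' rmse(c(0.3, 0.5), 0.4)  # 0.1
#' @export
rmse <- function(estimates, true) {
  if (length(estimates) == 0L) stop("`estimates` must be non-empty")
  sqrt(mean((estimates - true)^2))
}

# parameters whose recovery is tracked across replicates
.tracked <- function(T) c("alpha10", "psi11", paste0("delta", 2:T))

# aggregate a replicate-level results table into a condition report;
# RB/RMSE are computed over converged (optionally also improper) replicates
summarize_replicates <- function(results, truth, include_improper = FALSE) {
  status <- results$status
  counts <- c(attempted = nrow(results),
              converged = sum(status == "converged"),
              improper = sum(status == "improper"),
              nonconverged = sum(status == "nonconverged"),
              degenerate = sum(status == "degenerate"))
  difficulty <- 100 * (counts[["attempted"]] - counts[["converged"]]) /
    counts[["attempted"]]
  keep <- status == "converged"
  if (include_improper) keep <- keep | status == "improper"
  used <- results[keep, , drop = FALSE]

  pars <- intersect(names(truth), colnames(used))
  rb <- rmse_v <- rb_se <- stats::setNames(rep(NA_real_, length(pars)), pars)
  if (nrow(used) > 0L) {
    for (p in pars) {
      est <- used[[p]]
      if (truth[[p]] != 0) {
        rb[p] <- relative_bias(est, truth[[p]])
        rb_se[p] <- stats::sd(est) / (sqrt(length(est)) * abs(truth[[p]]))
      }
      rmse_v[p] <- rmse(est, truth[[p]])
    }
  }
  list(counts = counts, difficulty = unname(difficulty), rb = rb,
       rmse = rmse_v, rb_se = rb_se, n_used = nrow(used))
}

#' Run the Monte Carlo replicates of one simulation condition
#'
#' For each replicate: generate a panel under the condition's growth
#' specification and threshold set, fit the model, and classify the outcome
#' (`converged`, `improper`, `nonconverged`, or `degenerate` when an empty
#' category makes the sample thresholds undefined). Aggregates relative
#' bias, RMSE and Monte Carlo standard errors for the slope mean, slope
#' variance and scale factors over the usable replicates.
#'
#' @param cond A [condition()] row (or any list with `pattern`, `slope`,
#'   `categories`, `n` and optionally `id`).
#' @param reps Number of replicates.
#' @param base_seed Base seed of the run; replicate seeds come from
#'   [replicate_seed()], so reports are reproducible and independent across
#'   conditions.
#' @param include_improper Also pool improper solutions into RB/RMSE
#'   (sensitivity switch; default `FALSE`, converged proper solutions only).
#' @param weights Weighting scheme passed to [catlgm()].
#' @param cache_file Optional path to a CSV of replicate-level results; if it
#'   exists with at least `reps` rows the fits are not re-run (resumability),
#'   otherwise results are written there after the run.
#' @return Object of class `"condition_report"`: the condition, outcome
#'   `counts` (summing to `attempted`), the `difficulty` rate in percent
#'   (share of attempts that did not end in a converged proper solution),
#'   `rb`, `rmse` and `rb_se` per parameter, the `truth` used, and the
#'   replicate-level `results` table.
#' @export
run_condition <- function(cond, reps = 200L, base_seed = 1L,
                          include_improper = FALSE,
                          weights = c("asymptotic", "unit"),
                          cache_file = NULL) {
  stopifnot(reps >= 1L)
  weights <- match.arg(weights)
  id <- if (!is.null(cond$id)) cond$id else 1L
  spec <- condition_spec(cond$pattern, cond$slope)
  thr <- default_thresholds(cond$categories)
  tp <- true_parameters(spec)
  T <- length(spec$theta)
  truth <- stats::setNames(c(tp$alpha10, tp$psi11, tp$delta[-1L]),
                           .tracked(T))

  results <- NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    cached <- utils::read.csv(cache_file, stringsAsFactors = FALSE)
    if (nrow(cached) >= reps) results <- cached[seq_len(reps), , drop = FALSE]
  }
  if (is.null(results)) {
    rows <- lapply(seq_len(reps), function(r) {
      seed <- replicate_seed(base_seed, id, r)
      panel <- simulate_panel(spec, cond$n, thr, seed = seed)
      one_replicate(panel, r, seed, T, weights)
    })
    results <- do.call(rbind, rows)
    if (!is.null(cache_file)) {
      utils::write.csv(results, cache_file, row.names = FALSE)
    }
  }

  agg <- summarize_replicates(results, truth, include_improper)
  structure(
    c(list(condition = as.list(cond)[c("pattern", "slope", "categories", "n")],
           id = id, reps = reps, base_seed = base_seed,
           include_improper = include_improper, truth = truth,
           results = results),
      agg),
    class = "condition_report"
  )
}

# fit one generated panel and flatten the outcome to a results row
one_replicate <- function(panel, r, seed, T, weights) {
  est <- stats::setNames(rep(NA_real_, 4L + T), c(.tracked(T)[1:2],
         "psi00", "psi10", paste0("delta", 2:T), "discrepancy"))
  iterations <- 0L
  fit <- tryCatch(
    catlgm(panel, weights = weights),
    catlgm_degenerate = function(e) "degenerate",
    error = function(e) "nonconverged"
  )
  if (is.character(fit)) {
    status <- fit
    fit <- NULL
  }
  if (!is.null(fit)) {
    status <- fit$status
    iterations <- fit$iterations
    e <- fit$estimates
    est[c("alpha10", "psi11", "psi00", "psi10")] <-
      e[c("alpha10", "psi11", "psi00", "psi10")]
    est[paste0("delta", 2:T)] <- e[paste0("delta", 2:T)]
    est["discrepancy"] <- fit$discrepancy
  }
  cbind(data.frame(rep = r, seed = seed, status = status,
                   iterations = iterations, stringsAsFactors = FALSE),
        as.data.frame(as.list(est)))
}

#' @export
print.condition_report <- function(x, digits = 3, ...) {
  cond <- x$condition
  cat(sprintf("Condition: %s pattern, %s slope, %d categories, N = %d\n",
              cond$pattern, cond$slope, cond$categories, cond$n))
  cat(sprintf("%d replicates: %d converged, %d improper, %d nonconverged, %d degenerate\n",
              x$counts[["attempted"]], x$counts[["converged"]],
              x$counts[["improper"]], x$counts[["nonconverged"]],
              x$counts[["degenerate"]]))
  cat(sprintf("estimation difficulties: %.1f%%\n", x$difficulty))
  tab <- rbind(true = x$truth, RB = x$rb, `RB (MC SE)` = x$rb_se,
               RMSE = x$rmse)
  print(round(tab, digits))
  invisible(x)
}

#' Run a grid of simulation conditions
#'
#' @param grid Condition grid data frame (default the full 54-condition
#'   factorial from [condition_grid()]).
#' @param reps Replicates per condition.
#' @param base_seed Base seed of the run.
#' @param out_dir Optional directory: replicate-level results of each
#'   condition are cached there as CSV (and re-used on re-runs), making long
#'   runs resumable.
#' @param ... Passed to [run_condition()].
#' @return List of `"condition_report"` objects, one per grid row.
#' @export
run_grid <- function(grid = condition_grid(), reps = 200L, base_seed = 1L,
                     out_dir = NULL, ...) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  lapply(seq_len(nrow(grid)), function(i) {
    cond <- grid[i, , drop = FALSE]
    cache <- if (is.null(out_dir)) NULL else {
      file.path(out_dir, sprintf("condition-%02d-replicates.csv", cond$id))
    }
    run_condition(cond, reps = reps, base_seed = base_seed,
                  cache_file = cache, ...)
  })
}

#' Tabulate condition reports in the layout of the study tables
#'
#' Produces (a) a wide difficulties table — one row per pattern, slope level
#' and sample size, one column per category count — and (b) a long
#' estimates table with RB, Monte Carlo SE of RB, and RMSE per condition and
#' parameter, from which the per-pattern wide tables are formatted. Grid
#' cells not covered by `reports` appear as `NA` gap markers rather than
#' being dropped.
#'
#' @param reports List of `"condition_report"` objects.
#' @param grid The grid the reports are expected to cover (defaults to the
#'   full factorial).
#' @return List with `difficulties` (wide data frame) and `estimates` (long
#'   data frame with columns pattern, slope, n, categories, parameter, rb,
#'   rb_se, rmse).
#' @export
report_tables <- function(reports, grid = condition_grid()) {
  key <- function(p, s, c, n) paste(p, s, c, n, sep = "/")
  lookup <- new.env(parent = emptyenv())
  for (r in reports) {
    cond <- r$condition
    assign(key(cond$pattern, cond$slope, cond$categories, cond$n), r, lookup)
  }

  diff_rows <- unique(grid[, c("pattern", "slope", "n")])
  cats <- sort(unique(grid$categories))
  difficulties <- diff_rows
  for (cc in cats) difficulties[[paste0("cat", cc)]] <- NA_real_
  for (i in seq_len(nrow(diff_rows))) {
    for (cc in cats) {
      k <- key(diff_rows$pattern[i], diff_rows$slope[i], cc, diff_rows$n[i])
      if (exists(k, lookup)) {
        difficulties[i, paste0("cat", cc)] <- get(k, lookup)$difficulty
      }
    }
  }

  est_rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    k <- key(g$pattern, g$slope, g$categories, g$n)
    rep_i <- if (exists(k, lookup)) get(k, lookup) else NULL
    pars <- if (is.null(rep_i)) .tracked(4L) else names(rep_i$rb)
    for (p in pars) {
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        pattern = g$pattern, slope = g$slope, n = g$n,
        categories = g$categories, parameter = p,
        rb = if (is.null(rep_i)) NA_real_ else unname(rep_i$rb[p]),
        rb_se = if (is.null(rep_i)) NA_real_ else unname(rep_i$rb_se[p]),
        rmse = if (is.null(rep_i)) NA_real_ else unname(rep_i$rmse[p]),
        stringsAsFactors = FALSE)
    }
  }
  estimates <- do.call(rbind, est_rows)
  list(difficulties = difficulties, estimates = estimates)
}

#' Format the per-pattern estimates table
#'
#' Pivots the long estimates table of [report_tables()] for one change
#' pattern into the wide layout of the study's result tables: rows are
#' sample size x parameter, columns are slope level x category count x
#' (RB, RMSE).
#'
#' @param estimates Long estimates data frame from [report_tables()].
#' @param pattern Pattern to format.
#' @return Wide data frame.
#' @export
format_pattern_table <- function(estimates, pattern) {
  e <- estimates[estimates$pattern == pattern, ]
  rows <- unique(e[, c("n", "parameter")])
  out <- rows
  for (s in unique(e$slope)) {
    for (cc in sort(unique(e$categories))) {
      sub <- e[e$slope == s & e$categories == cc, ]
      m <- match(paste(rows$n, rows$parameter),
                 paste(sub$n, sub$parameter))
      out[[paste0(s, cc, "_rb")]] <- sub$rb[m]
      out[[paste0(s, cc, "_rmse")]] <- sub$rmse[m]
    }
  }
  out
}
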