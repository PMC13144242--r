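#' @export
print.dwls_fit <- function(x, digits = 4, ...) {
  cat("Categorical latent growth model (DWLS, delta parameterization)\n")
  if (!is.null(x$call)) {
    cat("call: ")
    print(x$call)
  }
  cat("status:", x$status, "\n")
  print(round(x$estimates, digits))
  invisible(x)
}

#' @export
coef.dwls_fit <- function(object, ...) object$estimates

#' @export
summary.catlgm <- function(object, ...) {
  est <- object$estimates
  T <- object$T
  delta <- c(1, est[paste0("delta", 2:T)])
  out <- list(
    call = object$call, status = object$status,
    estimates = est, discrepancy = object$discrepancy,
    iterations = object$iterations, n = object$n,
    categories = object$categories,
    latent_sd = unname(1 / delta),
    trajectory = unname(est["alpha10"] * object$loadings),
    boundary = isTRUE(object$moments$boundary)
  )
  class(out) <- "summary.catlgm"
  out
}

#' @export
print.summary.catlgm <- function(x, digits = 4, ...) {
  cat("Categorical latent growth model (DWLS, delta parameterization)\n")
  cat("call: ")
  print(x$call)
  cat("\nN =", x$n, " categories =", x$categories,
      " status =", x$status, "\n")
  if (x$boundary) cat("note: at least one polychoric at the search boundary\n")
  cat("\nEstimates:\n")
  print(round(x$estimates, digits))
  cat("\nImplied latent mean trajectory (origin at occasion 1):\n")
  print(round(x$trajectory, digits))
  cat("Implied latent SDs (1 / Delta_t):\n")
  print(round(x$latent_sd, digits))
  cat("\nDiscrepancy:", format(x$discrepancy, digits = digits),
      " (", x$iterations, "function evaluations )\n")
  invisible(x)
}

#' @export
fitted.dwls_fit <- function(object, ...) {
  est <- object$estimates
  T <- object$T
  n_tau <- object$n_tau
  implied_statistics(est[seq_len(n_tau)], est[["alpha10"]], est[["psi00"]],
                     est[["psi11"]], est[["psi10"]],
                     est[paste0("delta", 2:T)], object$loadings)
}

#' Residual differences between sample and implied statistics
#'
#' @param object A fitted `"catlgm"` object.
#' @param ... Unused.
#' @return Named vector: stacked sample statistics minus their model-implied
#'   values (thresholds first, then the unique polychoric correlations).
#' @export
residuals.catlgm <- function(object, ...) {
  s <- stack_statistics(object$moments$tau, object$moments$rho)
  r <- s - fitted(object)$stacked
  T <- object$T
  pairs <- utils::combn(T, 2L)
  names(r) <- c(
    paste0("tau", rep(seq_len(object$n_tau), T), "_t", rep(seq_len(T),
           each = object$n_tau)),
    paste0("rho_", pairs[1L, ], pairs[2L, ])
  )
  r
}

#' Simulate panels from a fitted categorical growth model
#'
#' Maps the fitted parameters back to a population growth specification: the
#' latent variance at occasion `t` is `1 / Delta_t^2`, so the occasion error
#' variance is `theta_t = 1 / Delta_t^2 - (psi00 + 2 lambda_t psi10 +
#' lambda_t^2 psi11)`. Requires a proper fit whose implied error variances
#' are positive.
#'
#' @param object A fitted `"catlgm"` object.
#' @param nsim Number of panels.
#' @param seed Optional seed.
#' @param n Subjects per panel; defaults to the fitted sample size.
#' @param ... Unused.
#' @return A panel, or list of panels when `nsim > 1`.
#' @export
simulate.catlgm <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  est <- object$estimates
  if (object$status != "converged") {
    stop("cannot simulate from a ", object$status, " fit")
  }
  l <- object$loadings
  delta <- c(1, est[paste0("delta", 2:object$T)])
  factor_var <- est[["psi00"]] + 2 * l * est[["psi10"]] + l^2 * est[["psi11"]]
  theta <- 1 / delta^2 - factor_var
  if (any(theta <= 0)) {
    stop("fitted scale factors imply non-positive error variances")
  }
  spec <- growth_spec(alpha00 = 0, alpha10 = est[["alpha10"]],
                      psi00 = est[["psi00"]], psi11 = est[["psi11"]],
                      psi10 = est[["psi10"]], theta = unname(theta),
                      loadings = l)
  simulate.growth_spec(spec, nsim = nsim, seed = seed, n = n,
                       thresholds = unname(est[seq_len(object$n_tau)]))
}

#' Plot the fitted latent trajectory
#'
#' Draws the estimated mean trajectory of the latent response variable on
#' the common scale, with a band of plus/minus one implied latent standard
#' deviation (`1 / Delta_t`) and the estimated invariant thresholds as
#' horizontal reference lines.
#'
#' @param x A fitted `"catlgm"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.catlgm <- function(x, ...) {
  est <- x$estimates
  l <- x$loadings
  mu <- est[["alpha10"]] * l
  sd <- 1 / c(1, est[paste0("delta", 2:x$T)])
  graphics::plot(l + 1, mu, type = "b", pch = 19,
                 ylim = range(mu - sd, mu + sd, est[seq_len(x$n_tau)]),
                 xlab = "occasion", ylab = "latent response (common scale)",
                 ...)
  graphics::lines(l + 1, mu + sd, lty = 2)
  graphics::lines(l + 1, mu - sd, lty = 2)
  graphics::abline(h = est[seq_len(x$n_tau)], col = "grey60", lty = 3)
  invisible(x)
}
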