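#' Model-implied thresholds and correlations under the delta parameterization
#'
#' For parameter values of the categorical linear growth model — invariant
#' thresholds `tau_c`, slope mean `alpha10` (the intercept mean is fixed at 0
#' for identification), growth-factor covariances and scale factors
#' `Delta_t` with `Delta_1 = 1` — returns the statistics the model implies
#' for the observed panel: per-occasion z-scale thresholds
#' `Delta_t * (tau_c - mu*_t)` with `mu*_t = alpha10 * lambda_t`, and latent
#' correlations `Delta_t * Delta_u * (psi00 + (lambda_t + lambda_u) psi10 +
#' lambda_t lambda_u psi11)`. At the solution `Delta_t` equals the inverse
#' latent standard deviation at occasion `t`.
#'
#' @param tau Invariant thresholds (length `C - 1`, increasing).
#' @param alpha10 Slope mean.
#' @param psi00,psi11,psi10 Growth-factor (co)variances.
#' @param delta Scale factors for occasions `2:T` (positive); `Delta_1 = 1`
#'   is implicit.
#' @param loadings Growth loadings (length `T`).
#' @return List with `thresholds` (`T x (C-1)` matrix), `rho` (`T x T`
#'   matrix) and `stacked` (vector conformable with [sample_moments()]).
#' @examples
#' implied_statistics(tau = 0, alpha10 = 0.4,
#'                    psi00 = 0.5, psi11 = 0.1, psi10 = 0,
#'                    delta = 1 / sqrt(c(1.2, 1.8, 2.8)), loadings = 0:3)
#' @export
implied_statistics <- function(tau, alpha10, psi00, psi11, psi10, delta,
                               loadings) {
  T <- length(loadings)
  if (length(delta) != T - 1L) {
    stop("`delta` must supply scale factors for occasions 2:T")
  }
  if (any(delta <= 0)) stop("scale factors must be positive")
  d <- c(1, delta)
  mu <- alpha10 * loadings
  cov <- psi00 + outer(loadings, loadings) * psi11 +
    (outer(loadings, rep(1, T)) + outer(rep(1, T), loadings)) * psi10
  th <- outer(d, rep(1, length(tau))) *
    (outer(rep(1, T), tau) - outer(mu, rep(1, length(tau))))
  rho <- outer(d, d) * cov
  diag(rho) <- 1
  list(thresholds = th, rho = rho,
       stacked = stack_statistics(split(th, row(th)), rho))
}

# internal parameter packing: c(tau_1..tau_{C-1}, alpha10, psi00, psi10,
# psi11, log(Delta_2)..log(Delta_T)); psi entries deliberately unconstrained
# so that improper solutions can occur and be classified, as in practice
unpack_par <- function(par, n_tau, T) {
  # clamp log scale factors so extreme line-search steps cannot underflow
  # exp() to zero (or overflow) and abort the optimiser
  logd <- pmin(pmax(par[n_tau + 4L + seq_len(T - 1L)], -30), 30)
  list(tau = par[seq_len(n_tau)],
       alpha10 = par[n_tau + 1L],
       psi00 = par[n_tau + 2L],
       psi10 = par[n_tau + 3L],
       psi11 = par[n_tau + 4L],
       delta = exp(logd))
}

dwls_objective <- function(par, s, w, n_tau, T, loadings) {
  p <- unpack_par(par, n_tau, T)
  imp <- implied_statistics(p$tau, p$alpha10, p$psi00, p$psi11, p$psi10,
                            p$delta, loadings)
  # soft penalty steers the optimizer away from implied correlations
  # outside (-1, 1); the quadratic discrepancy itself is defined everywhere
  off <- imp$rho[upper.tri(imp$rho)]
  pen <- 1e4 * sum(pmax(abs(off) - 0.999, 0)^2)
  val <- sum((s - imp$stacked)^2 / w) + pen
  if (!is.finite(val)) 1e10 else val
}

# moment-based starting values: stage-1 thresholds at occasion 1; slope from
# the drift of the thresholds; Delta from the scaling calculus (unit-length
# ratios), which is exact in the ordinal population case
dwls_starts <- function(moments, loadings) {
  tau0 <- moments$tau[[1L]]
  T <- length(moments$tau)
  drift <- vapply(seq_len(T), function(t) {
    mean(tau0 - moments$tau[[t]])
  }, numeric(1))
  alpha0 <- sum(loadings * drift) / sum(loadings^2)
  psi00_0 <- min(max(moments$rho[1L, 2L], 0.05), 0.95)
  w_t <- if (moments$categories == 2L) {
    binary_unit_length(stats::pnorm(vapply(moments$tau, `[`, numeric(1), 1L)))
  } else {
    vapply(moments$tau, ordinal_unit_length, numeric(1))
  }
  d0 <- log(w_t[-1L] / w_t[1L])
  list(
    c(tau0, alpha0, psi00_0, 0, 0.05, d0),
    c(tau0, alpha0, 0.3, 0, 0.1, rep(0, T - 1L)),
    c(tau0, alpha0 / 2, 0.5, 0, 0.02, d0 / 2)
  )
}

#' Diagonally weighted least-squares fit of the categorical growth model
#'
#' Stage 3 of the estimator: minimises the weighted quadratic discrepancy
#' between the stacked sample statistics (thresholds, then polychoric
#' correlations) and their model-implied counterparts, with the inverse
#' estimated asymptotic variances as diagonal weights and `Delta_1` fixed at
#' 1. Optimisation is quasi-Newton (BFGS) on log scale factors with
#' unconstrained growth-factor covariances, from a moment-based start and two
#' fixed fallback starts; the first start that converges is accepted.
#'
#' @param moments A [sample_moments()] or [population_statistics()] object.
#' @param loadings Growth loadings; default `0:(T-1)`.
#' @param control List: `maxit` (default 500) and `reltol` (default 1e-10)
#'   passed to [stats::optim()].
#' @return Object of class `"dwls_fit"`: list with `estimates` (named vector:
#'   thresholds, `alpha10`, `psi00`, `psi10`, `psi11`, `delta2 ...`),
#'   `status` (`"converged"`, `"improper"` — converged but with a negative
#'   variance or non-PSD factor covariance — or `"nonconverged"`),
#'   `discrepancy`, `iterations`, and the index of the accepted start.
#' @export
fit_dwls <- function(moments, loadings = NULL, control = list()) {
  T <- length(moments$tau)
  n_tau <- length(moments$tau[[1L]])
  loadings <- loadings %||% (seq_len(T) - 1)
  ctrl <- list(maxit = control$maxit %||% 500L,
               reltol = control$reltol %||% 1e-10)
  s <- stack_statistics(moments$tau, moments$rho)
  w <- moments$acov %||% rep(1, length(s))

  best <- NULL
  status <- "nonconverged"
  start_used <- NA_integer_
  starts <- dwls_starts(moments, loadings)
  for (k in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[k]], dwls_objective, method = "BFGS",
                   control = ctrl, s = s, w = w, n_tau = n_tau, T = T,
                   loadings = loadings),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
    if (opt$convergence == 0L) {
      best <- opt
      status <- "converged"
      start_used <- k
      break
    }
  }

  if (is.null(best)) {
    est <- rep(NA_real_, n_tau + 4L + (T - 1L))
    p <- NULL
  } else {
    p <- unpack_par(best$par, n_tau, T)
    est <- c(p$tau, p$alpha10, p$psi00, p$psi10, p$psi11, p$delta)
  }
  names(est) <- c(paste0("tau", seq_len(n_tau)), "alpha10", "psi00",
                  "psi10", "psi11", paste0("delta", 2:T))

  if (status == "converged") {
    improper <- p$psi11 < 0 || p$psi00 < 0 ||
      p$psi00 * p$psi11 - p$psi10^2 < 0
    if (improper) status <- "improper"
  }

  structure(
    list(estimates = est, status = status,
         discrepancy = if (is.null(best)) NA_real_ else best$value,
         iterations = if (is.null(best)) 0L else unname(best$counts[1L]),
         start = start_used, loadings = loadings, n_tau = n_tau, T = T),
    class = "dwls_fit"
  )
}

#' Fit a latent growth model to a longitudinal categorical panel
#'
#' The front door of the package: estimates the linear latent growth model
#' from an `N x T` panel of integer categories by the three-stage procedure —
#' univariate probit thresholds, pairwise polychoric correlations with
#' thresholds fixed, then diagonally weighted least squares under the delta
#' parameterization (`Delta_1 = 1`, intercept mean fixed at 0, invariant
#' thresholds estimated freely).
#'
#' @param panel Integer panel matrix (categories `0:(C-1)`), e.g. from
#'   [simulate_panel()] or [read_panel()].
#' @param loadings Growth loadings; default `0:(T-1)` (linear growth).
#' @param weights `"asymptotic"` (default) or `"unit"`; see
#'   [asymptotic_weights()].
#' @param categories Number of categories (taken from the panel attribute by
#'   default).
#' @param control Optimiser control, see [fit_dwls()].
#' @return Object of class `"catlgm"` with `print()`, `summary()`, `coef()`,
#'   `fitted()`, `residuals()`, `simulate()` and `plot()` methods. Key
#'   components: `estimates`, `status`, `moments`, `discrepancy`.
#' @examples
#' panel <- simulate_panel(condition_spec("shift", "large"), n = 500,
#'                         thresholds = default_thresholds(3), seed = 7)
#' fit <- catlgm(panel)
#' coef(fit)
#' @export
catlgm <- function(panel, loadings = NULL, weights = c("asymptotic", "unit"),
                   categories = NULL, control = list()) {
  weights <- match.arg(weights)
  moments <- sample_moments(panel, categories = categories, weights = weights)
  fit <- fit_dwls(moments, loadings = loadings, control = control)
  structure(
    c(fit, list(moments = moments, n = moments$n,
                categories = moments$categories, call = match.call())),
    class = c("catlgm", "dwls_fit")
  )
}
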