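#' Per-occasion sample thresholds of a categorical panel
#'
#' Stage 1 of the estimator: standard-normal quantiles of the empirical
#' cumulative category proportions of every occasion.
#'
#' @param panel Integer panel matrix (`N x T`, categories `0:(C-1)`).
#' @param categories Number of categories; taken from the panel attribute by
#'   default.
#' @return List of `T` threshold vectors (each of length `C - 1`).
#' @details An occasion with an empty category signals an error of class
#'   `"catlgm_degenerate"`, which the simulation layer records as an
#'   estimation difficulty.
#' @export
sample_thresholds <- function(panel, categories = NULL) {
  categories <- categories %||% attr(panel, "categories") %||%
    (max(panel) + 1L)
  lapply(seq_len(ncol(panel)), function(t) {
    counts <- tabulate(panel[, t] + 1L, nbins = categories)
    if (any(counts == 0L)) {
      stop(degenerate_error(sprintf(
        "empty category at occasion %d: thresholds undefined", t)))
    }
    z_thresholds(counts / sum(counts))
  })
}

# stacking order of the fitted statistics: thresholds occasion-major
# (t1 c1..c_{C-1}, t2 ..., tT), then the unique correlations in the order of
# utils::combn(T, 2): (1,2), (1,3), ..., (T-1,T)
stack_statistics <- function(tau, rho) {
  pairs <- utils::combn(nrow(rho), 2L)
  c(unlist(tau), rho[t(pairs)])
}

#' Sample thresholds, polychoric correlations and asymptotic weights
#'
#' Runs both estimation stages on a panel: univariate thresholds per
#' occasion, then the pairwise polychoric correlations with thresholds held
#' fixed, together with the estimated asymptotic variances of the stacked
#' statistics that serve as diagonal weights for the least-squares fit.
#'
#' @param panel Integer panel matrix.
#' @param categories Number of categories (panel attribute by default).
#' @param weights `"asymptotic"` (delta-method / observed-information
#'   variances) or `"unit"` (unweighted least squares).
#' @return Object of class `"sample_moments"`: list with `tau` (list of
#'   threshold vectors), `rho` (`T x T` correlation matrix), `acov` (stacked
#'   asymptotic-variance vector), `n`, `categories` and a `boundary` flag
#'   marking correlations at the search boundary.
#' @export
sample_moments <- function(panel, categories = NULL,
                           weights = c("asymptotic", "unit")) {
  weights <- match.arg(weights)
  categories <- categories %||% attr(panel, "categories") %||%
    (max(panel) + 1L)
  T <- ncol(panel)
  tau <- sample_thresholds(panel, categories)

  rho <- diag(T)
  boundary <- FALSE
  pairs <- utils::combn(T, 2L)
  for (k in seq_len(ncol(pairs))) {
    t <- pairs[1L, k]
    u <- pairs[2L, k]
    r <- polychoric(panel[, t], panel[, u], tx = tau[[t]], ty = tau[[u]])
    boundary <- boundary || isTRUE(attr(r, "boundary"))
    rho[t, u] <- rho[u, t] <- as.numeric(r)
  }

  out <- structure(
    list(tau = tau, rho = rho, acov = NULL, n = nrow(panel),
         categories = categories, boundary = boundary),
    class = "sample_moments"
  )
  out$acov <- if (weights == "unit") {
    rep(1, length(stack_statistics(tau, rho)))
  } else {
    asymptotic_weights(panel, out)
  }
  out
}

#' @export
print.sample_moments <- function(x, digits = 3, ...) {
  cat("Sample moments of a categorical panel (N =", x$n, ")\n")
  cat("thresholds by occasion:\n")
  for (t in seq_along(x$tau)) {
    cat("  t", t, ": ", paste(round(x$tau[[t]], digits), collapse = ", "),
        "\n", sep = "")
  }
  cat("polychoric correlations:\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Asymptotic variances of the stacked thresholds and correlations
#'
#' Estimated asymptotic variances used as diagonal weights by the DWLS fit.
#' Threshold variances come from the delta method for a probit quantile,
#' `Var(tau_hat) = P(1 - P) / (N * phi(tau)^2)` with `P` the cumulative
#' proportion below the cut. Correlation variances are inverse observed
#' information of the stage-2 pairwise likelihood at the estimate (numerical
#' second derivative with thresholds fixed). If any entry is non-finite or
#' non-positive (e.g. a boundary correlation), the whole vector falls back to
#' unit weights with a warning, i.e. unweighted least squares.
#'
#' @param panel Integer panel matrix.
#' @param moments A [sample_moments()] object (stage-1/2 estimates).
#' @return Positive vector conformable with the stacked statistics.
#' @export
asymptotic_weights <- function(panel, moments) {
  n <- nrow(panel)
  T <- ncol(panel)
  var_tau <- unlist(lapply(seq_len(T), function(t) {
    tau <- moments$tau[[t]]
    P <- stats::pnorm(tau)
    P * (1 - P) / (n * stats::dnorm(tau)^2)
  }))

  pairs <- utils::combn(T, 2L)
  var_rho <- vapply(seq_len(ncol(pairs)), function(k) {
    t <- pairs[1L, k]
    u <- pairs[2L, k]
    tab <- table(factor(panel[, t], levels = 0:(moments$categories - 1L)),
                 factor(panel[, u], levels = 0:(moments$categories - 1L)))
    tab <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
    rho <- moments$rho[t, u]
    h <- min(1e-3, (0.999 - abs(rho)) / 2)
    if (h <= 0) return(NA_real_)
    f0 <- polychoric_nll(rho, tab, moments$tau[[t]], moments$tau[[u]])
    fp <- polychoric_nll(rho + h, tab, moments$tau[[t]], moments$tau[[u]])
    fm <- polychoric_nll(rho - h, tab, moments$tau[[t]], moments$tau[[u]])
    info <- (fp - 2 * f0 + fm) / h^2
    if (!is.finite(info) || info <= 0) NA_real_ else 1 / info
  }, numeric(1))

  acov <- c(var_tau, var_rho)
  if (any(!is.finite(acov)) || any(acov <= 0)) {
    warning("singular or boundary asymptotic variances; ",
            "falling back to unit weights (unweighted least squares)")
    acov <- rep(1, length(acov))
  }
  acov
}

#' Exact population statistics of a condition
#'
#' The analytic counterparts of [sample_moments()]: population z-scale
#' thresholds `(tau_c - mu*_t) / sqrt(sigma*_t)` and the latent correlation
#' matrix implied by a growth specification and an invariant threshold set.
#' Used as a noiseless input to the fit for identification checks.
#'
#' @param spec A [growth_spec()].
#' @param thresholds Invariant cut points on the latent scale.
#' @return A `"sample_moments"` object with unit weights and `n = Inf`.
#' @export
population_statistics <- function(spec, thresholds) {
  m <- implied_moments(spec)
  sd <- sqrt(diag(m$cov))
  tau <- lapply(seq_along(sd), function(t) (thresholds - m$mean[t]) / sd[t])
  rho <- stats::cov2cor(m$cov)
  structure(
    list(tau = tau, rho = rho,
         acov = rep(1, length(stack_statistics(tau, rho))),
         n = Inf, categories = length(thresholds) + 1L, boundary = FALSE),
    class = "sample_moments"
  )
}
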