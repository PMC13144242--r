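#' Population specification of a linear latent growth model
#'
#' Bundles the parameters of the linear growth model for the latent response
#' variable `y*_it = eta0_i + eta1_i * lambda_t + e_it`: the growth-factor
#' means (`alpha00`, `alpha10`), their covariance matrix (`psi00`, `psi11`,
#' `psi10`), the per-occasion error variances `theta_t` and the loadings
#' `lambda_t` (default `t - 1`, centring the intercept at the first
#' occasion).
#'
#' @param alpha00 Intercept mean.
#' @param alpha10 Slope mean.
#' @param psi00 Intercept variance (non-negative).
#' @param psi11 Slope variance (non-negative).
#' @param psi10 Intercept-slope covariance.
#' @param theta Positive per-occasion error variances; its length sets the
#'   number of occasions `T >= 2`.
#' @param loadings Growth loadings, default `0:(T-1)`.
#' @return An object of class `"growth_spec"`.
#' @examples
#' growth_spec(alpha00 = -0.6, alpha10 = 0.4)
#' @export
growth_spec <- function(alpha00, alpha10, psi00 = 0.5, psi11 = 0.1,
                        psi10 = 0, theta = c(0.5, 0.6, 0.9, 1.4),
                        loadings = seq_along(theta) - 1) {
  if (length(theta) < 2L) stop("at least two occasions are required")
  if (any(theta <= 0)) stop("error variances `theta` must be positive")
  if (length(loadings) != length(theta)) {
    stop("`loadings` and `theta` must have one entry per occasion")
  }
  if (psi00 < 0 || psi11 < 0 || psi00 * psi11 - psi10^2 < -1e-12) {
    stop("growth-factor covariance matrix must be positive semidefinite")
  }
  structure(
    list(alpha00 = alpha00, alpha10 = alpha10, psi00 = psi00, psi11 = psi11,
         psi10 = psi10, theta = theta, loadings = loadings),
    class = "growth_spec"
  )
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("Linear growth model for the latent response variable\n")
  cat("  means:      alpha00 =", x$alpha00, " alpha10 =", x$alpha10, "\n")
  cat("  covariance: psi00 =", x$psi00, " psi11 =", x$psi11,
      " psi10 =", x$psi10, "\n")
  cat("  theta:     ", paste(x$theta, collapse = ", "), "\n")
  cat("  loadings:  ", paste(x$loadings, collapse = ", "), "\n")
  invisible(x)
}

#' Model-implied moments of the latent response variables
#'
#' Computes the per-occasion means, variances and covariances of `y*` implied
#' by a linear growth specification:
#' `mu*_t = alpha00 + alpha10 * lambda_t`,
#' `sigma*_t = psi00 + 2 lambda_t psi10 + lambda_t^2 psi11 + theta_t`, and
#' `sigma*_tu = psi00 + (lambda_t + lambda_u) psi10 + lambda_t lambda_u psi11`.
#'
#' @param spec A [growth_spec()].
#' @return An object of class `"population_moments"`: list with `mean`
#'   (length `T`) and `cov` (`T x T` positive-definite matrix).
#' @examples
#' implied_moments(growth_spec(-0.6, 0.4))
#' @export
implied_moments <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  l <- spec$loadings
  mu <- spec$alpha00 + spec$alpha10 * l
  cov <- spec$psi00 + outer(l, l) * spec$psi11 +
    (outer(l, rep(1, length(l))) + outer(rep(1, length(l)), l)) * spec$psi10
  cov <- cov + diag(spec$theta)
  if (inherits(try(chol(cov), silent = TRUE), "try-error")) {
    stop("implied covariance matrix is not positive definite")
  }
  structure(list(mean = mu, cov = cov), class = "population_moments")
}

#' @export
print.population_moments <- function(x, digits = 3, ...) {
  cat("Implied latent means:\n")
  print(round(x$mean, digits))
  cat("Implied latent covariance:\n")
  print(round(x$cov, digits))
  invisible(x)
}

#' Generation thresholds for a given number of categories
#'
#' Symmetric population thresholds used to discretise the latent response
#' variable: `0` for two categories, `(-0.83, 0.83)` for three and
#' `(-1.25, 0, 1.25)` for four.
#'
#' @param categories Number of observed categories (2, 3 or 4).
#' @return Numeric vector of `categories - 1` strictly increasing cut points.
#' @export
default_thresholds <- function(categories) {
  switch(as.character(categories),
         "2" = 0,
         "3" = c(-0.83, 0.83),
         "4" = c(-1.25, 0, 1.25),
         stop("`categories` must be 2, 3 or 4"))
}

# intercept means by pattern x slope level; the slope mean then traces the
# remaining occasion means mu*_t = alpha00 + alpha10 * (t - 1)
.pattern_intercepts <- list(
  shift    = c(large = -0.60, small = -0.15),
  increase = c(large = -1.20, small = -0.30),
  decrease = c(large = 0.00,  small = 0.00)
)
.slope_means <- c(large = 0.40, small = 0.10)

#' Growth specification of a named simulation condition
#'
#' Maps a change pattern (`"shift"`, `"increase"`, `"decrease"`) and a slope
#' level (`"large"` = 0.40, `"small"` = 0.10) to the population growth
#' specification of the simulation design: the pattern and slope level fix
#' the occasion means, and the covariance side is always
#' `psi00 = 0.5, psi11 = 0.1, psi10 = 0` with error variances
#' `theta = (0.5, 0.6, 0.9, 1.4)` over four occasions, so the latent
#' variances increase over time as `(1.0, 1.2, 1.8, 2.8)`.
#'
#' @param pattern One of `"shift"`, `"increase"`, `"decrease"`.
#' @param slope One of `"large"`, `"small"`.
#' @return A [growth_spec()].
#' @examples
#' implied_moments(condition_spec("increase", "small"))$mean  # -0.3 ... 0.0
#' @export
condition_spec <- function(pattern = c("shift", "increase", "decrease"),
                           slope = c("large", "small")) {
  pattern <- match.arg(pattern)
  slope <- match.arg(slope)
  growth_spec(alpha00 = .pattern_intercepts[[pattern]][[slope]],
              alpha10 = .slope_means[[slope]])
}

#' Simulation condition descriptor
#'
#' @param pattern Change pattern: `"shift"`, `"increase"` or `"decrease"`.
#' @param slope Slope-mean level: `"large"` (0.40) or `"small"` (0.10).
#' @param categories Number of observed categories (2, 3 or 4).
#' @param n Sample size per replicate.
#' @param id Integer condition id used to derive replicate seeds.
#' @return A one-row data frame describing the condition.
#' @export
condition <- function(pattern, slope, categories, n, id = 1L) {
  condition_spec(pattern, slope)  # validates labels
  default_thresholds(categories)
  data.frame(id = as.integer(id), pattern = pattern, slope = slope,
             categories = as.integer(categories), n = as.integer(n),
             stringsAsFactors = FALSE)
}

#' The full factorial grid of simulation conditions
#'
#' Crosses slope level (2) x change pattern (3) x number of categories (3) x
#' sample size (3) into the 54 conditions of the simulation design, each with
#' a distinct id from which per-replicate seeds are derived.
#'
#' @param n Sample sizes; default `c(100, 200, 1000)`.
#' @return A 54-row data frame with columns `id`, `pattern`, `slope`,
#'   `categories`, `n`.
#' @export
condition_grid <- function(n = c(100L, 200L, 1000L)) {
  grid <- expand.grid(
    n = as.integer(n),
    categories = c(2L, 3L, 4L),
    slope = c("large", "small"),
    pattern = c("shift", "increase", "decrease"),
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("pattern", "slope", "categories", "n")]
  cbind(id = seq_len(nrow(grid)), grid)
}

#' True parameter values of a condition under the delta parameterization
#'
#' Returns the generating slope mean and variance together with the
#' population scale factors `Delta_t = sqrt(sigma*_1 / sigma*_t)` (the
#' inverse latent standard deviations after fixing `Delta_1 = 1`), the
#' targets against which relative bias and RMSE are computed.
#'
#' @param spec A [growth_spec()], or a pattern label (with `slope`) naming a
#'   study condition.
#' @param slope Slope level, used only when `spec` is a pattern label.
#' @return List with `alpha10`, `psi11` and `delta` (length `T`, first entry
#'   1).
#' @export
true_parameters <- function(spec, slope = NULL) {
  if (is.character(spec)) spec <- condition_spec(spec, slope)
  v <- diag(implied_moments(spec)$cov)
  list(alpha10 = spec$alpha10, psi11 = spec$psi11,
       delta = sqrt(v[1L] / v))
}

#' Deterministic per-replicate seed
#'
#' Counter-based scheme giving every (condition, replicate) pair of a run its
#' own reproducible seed below `2^31`: pairs are distinct for up to 20,010
#' replicates per condition, so conditions can be re-run or resumed
#' independently.
#'
#' @param base_seed Base seed of the run (small integer).
#' @param condition_id Condition id (see [condition_grid()]).
#' @param rep Replicate index (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, condition_id, rep) {
  as.integer((base_seed %% 2003) * 1000003 + condition_id * 20011 + rep)
}
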