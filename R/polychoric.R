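# Cell probabilities of a bivariate standard normal cross-classified by
# threshold sets tx (rows) and ty (columns). Interior CDF values come from
# mvtnorm; margins reduce to univariate normals.
bvn_cell_probs <- function(tx, ty, rho) {
  a <- c(-Inf, tx, Inf)
  b <- c(-Inf, ty, Inf)
  na <- length(a)
  nb <- length(b)
  F <- matrix(0, na, nb)  # F[i, j] = P(X <= a[i], Y <= b[j])
  F[na, ] <- stats::pnorm(b)
  F[, nb] <- stats::pnorm(a)
  corr <- matrix(c(1, rho, rho, 1), 2L)
  for (i in seq(2L, na - 1L)) {
    for (j in seq(2L, nb - 1L)) {
      F[i, j] <- mvtnorm::pmvnorm(upper = c(a[i], b[j]), corr = corr,
                                  keepAttr = FALSE)
    }
  }
  P <- F[-1L, -1L, drop = FALSE] - F[-na, -1L, drop = FALSE] -
    F[-1L, -nb, drop = FALSE] + F[-na, -nb, drop = FALSE]
  pmax(P, 0)
}

# negative log-likelihood of a contingency table at correlation rho,
# thresholds held fixed (stage 2 of the two-stage estimator)
polychoric_nll <- function(rho, tab, tx, ty) {
  P <- bvn_cell_probs(tx, ty, rho)
  -sum(tab * log(pmax(P, 1e-300)))
}

#' Polychoric (tetrachoric) correlation with fixed thresholds
#'
#' Maximum-likelihood estimate of the correlation of two latent standard
#' normal variables underlying a cross-tabulation of two ordinal (or binary)
#' variables, with the thresholds held fixed at their univariate estimates —
#' the second stage of the two-stage estimator behind diagonally weighted
#' least squares. The bivariate-normal likelihood of the observed table is
#' maximised over the correlation by golden-section/parabolic search on
#' (-0.999, 0.999).
#'
#' @param x Integer category vector (values `0:(Cx-1)`), or a contingency
#'   table (matrix of counts) in which case `y` is omitted.
#' @param y Integer category vector.
#' @param tx,ty Thresholds of each margin; when `NULL` they are estimated
#'   from the observed margins of the table.
#' @param tol Convergence tolerance of the one-dimensional search.
#' @return The estimated correlation, with attribute `boundary` set to `TRUE`
#'   when the estimate lies against the search boundary (near-perfect
#'   association, e.g. empty complementary cells).
#' @examples
#' tab <- rbind(c(200, 300), c(200, 300))  # independence
#' polychoric(tab)
#' @export
polychoric <- function(x, y = NULL, tx = NULL, ty = NULL, tol = 1e-7) {
  if (is.matrix(x)) {
    tab <- x
  } else {
    cx <- if (is.null(tx)) max(x) + 1L else length(tx) + 1L
    cy <- if (is.null(ty)) max(y) + 1L else length(ty) + 1L
    tab <- table(factor(x, levels = 0:(cx - 1L)),
                 factor(y, levels = 0:(cy - 1L)))
    tab <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  }
  n <- sum(tab)
  if (n <= 0) stop("empty contingency table")
  margin_tau <- function(counts) {
    cum <- cumsum(counts)[-length(counts)] / sum(counts)
    if (any(cum <= 0) || any(cum >= 1)) {
      stop(degenerate_error("empty category: thresholds undefined for this margin"))
    }
    stats::qnorm(cum)
  }
  if (is.null(tx)) tx <- margin_tau(rowSums(tab))
  if (is.null(ty)) ty <- margin_tau(colSums(tab))

  opt <- stats::optimize(polychoric_nll, interval = c(-0.999, 0.999),
                         tab = tab, tx = tx, ty = ty, tol = tol)
  rho <- opt$minimum
  structure(rho, boundary = abs(rho) > 0.999 - 5e-3)
}
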