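#' Z-scale thresholds from category proportions
#'
#' Maps the category proportions of one measurement occasion to thresholds of
#' the latent response variable on the z-scale, i.e. the standard-normal
#' quantiles of the cumulative proportions at the `C - 1` cut points.
#'
#' @param p Numeric vector of category proportions for a single occasion
#'   (length `C >= 2`). Must be strictly positive and sum to one.
#' @param tol Tolerance for the sum-to-one check.
#'
#' @return Numeric vector of `C - 1` strictly increasing thresholds.
#'
#' @details A proportion of zero (or a cumulative proportion of 0 or 1) means
#'   a category was never, or always, observed; the latent scale is then not
#'   identified from that margin and an error of class
#'   `"catlgm_degenerate"` is signalled rather than clamping the input, so
#'   that simulation code can count the replicate as an estimation
#'   difficulty.
#'
#' @examples
#' z_thresholds(c(0.5, 0.5))          # 0
#' z_thresholds(c(0.70, 0.30))        # 0.524
#' z_thresholds(c(0.2033, 0.5934, 0.2033))
#' @export
z_thresholds <- function(p, tol = 1e-10) {
  if (!is.numeric(p) || length(p) < 2L) {
    stop("`p` must be a numeric vector of at least two category proportions")
  }
  if (abs(sum(p) - 1) > tol) {
    stop("category proportions must sum to 1 (got ", format(sum(p)), ")")
  }
  if (any(p <= 0)) {
    stop(degenerate_error("all category proportions must be strictly positive"))
  }
  cum <- cumsum(p)[-length(p)]
  if (any(cum <= 0) || any(cum >= 1)) {
    stop(degenerate_error("cumulative proportions of 0 or 1 leave the threshold undefined"))
  }
  stats::qnorm(cum)
}

# structured error so callers can classify unusable replicates
degenerate_error <- function(msg) {
  errorCondition(msg, class = c("catlgm_degenerate", "catlgm_error"))
}

#' Unit length of a binary latent response variable on the z-scale
#'
#' For a binary indicator the inter-threshold distance does not exist, so the
#' scale unit is taken from the standard deviation of the observed variable:
#' `w = sqrt(1 / (p * (1 - p)))`, the reciprocal of the Bernoulli standard
#' deviation. It is smallest (exactly 2) at `p = 0.5` and grows as the
#' response rate moves towards 0 or 1 — the unit length is tied to the
#' location of the threshold, which is the root of the scaling problems of
#' binary growth models.
#'
#' @param p Probability of the positive response, strictly inside (0, 1).
#'   Vectorised.
#' @return Positive unit length(s).
#' @examples
#' binary_unit_length(0.5)    # 2
#' binary_unit_length(0.159)  # 2.735
#' @export
binary_unit_length <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)")
  }
  sqrt(1 / (p * (1 - p)))
}

#' Unit length of an ordinal latent response variable on the z-scale
#'
#' The scale unit of an ordinal indicator is the distance between two of its
#' z-scale thresholds. By default the first two thresholds are used (the
#' lower one anchoring the origin, the gap to the next the unit); any other
#' pair can be selected via `pair`.
#'
#' @param thresholds Strictly increasing numeric vector of at least two
#'   z-scale thresholds.
#' @param pair Integer vector of length two: which thresholds delimit the
#'   unit. Default `c(1, 2)`.
#' @return Positive unit length.
#' @examples
#' ordinal_unit_length(c(-0.83, 0.83))     # 1.66
#' ordinal_unit_length(c(-1.25, 0, 1.25))  # 1.25 (first two thresholds)
#' @export
ordinal_unit_length <- function(thresholds, pair = c(1L, 2L)) {
  if (length(thresholds) < 2L) {
    stop("an ordinal unit needs at least two thresholds; ",
         "for a binary indicator use binary_unit_length()")
  }
  if (any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be strictly increasing")
  }
  pair <- as.integer(pair)
  if (length(pair) != 2L || any(pair < 1L) || any(pair > length(thresholds)) ||
      pair[1L] >= pair[2L]) {
    stop("`pair` must index two distinct thresholds in increasing order")
  }
  thresholds[pair[2L]] - thresholds[pair[1L]]
}

#' Common-scale standard deviations from per-occasion unit lengths
#'
#' Once every occasion's z-scale unit length `w_t` is known, imposing a common
#' unit `w` (the unit of the reference occasion) rescales the latent response
#' variable at occasion `t` to standard deviation
#' `sqrt(s*_t) = w_reference / w_t`, so that `w_t * sqrt(s*_t) = w` for all
#' `t` and `sqrt(s*) = 1` at the reference occasion.
#'
#' @param unit_lengths Positive numeric vector of per-occasion unit lengths.
#' @param reference Index of the reference occasion (default 1).
#' @return Numeric vector of common-scale standard deviations.
#' @examples
#' common_scale_sds(c(2.735, 2.0, 2.735))  # 1, 1.368, 1
#' @export
common_scale_sds <- function(unit_lengths, reference = 1L) {
  if (any(!is.finite(unit_lengths)) || any(unit_lengths <= 0)) {
    stop("`unit_lengths` must be positive and finite")
  }
  reference <- as.integer(reference)
  if (reference < 1L || reference > length(unit_lengths)) {
    stop("`reference` out of range")
  }
  unit_lengths[reference] / unit_lengths
}

#' Common-scale means from standard deviations and a shared threshold
#'
#' Threshold invariance places one common-scale threshold (the anchor) at the
#' same location for every occasion; writing the anchor as
#' `ybar*_t + sqrt(s*_t) * tau^z_t` for each occasion and solving gives
#' `ybar*_t = anchor - sqrt(s*_t) * tau^z_t`.
#'
#' @param sds Per-occasion common-scale standard deviations.
#' @param z_thresholds Per-occasion z-scale location of the anchored
#'   threshold (one value per occasion, same cut at each occasion).
#' @param anchor Common-scale value of that threshold; default 0 (first
#'   threshold fixed at the origin).
#' @return Numeric vector of common-scale means.
#' @examples
#' common_scale_means(c(1, 1.368, 1), c(-1, 0, 1))  # 1, 0, -1
#' @export
common_scale_means <- function(sds, z_thresholds, anchor = 0) {
  if (length(sds) != length(z_thresholds)) {
    stop("`sds` and `z_thresholds` must have the same length")
  }
  anchor - sds * z_thresholds
}

#' Common-scale summary of a longitudinal categorical variable
#'
#' Runs the full observed-scale-reference calculus on a set of per-occasion
#' category proportions: z-scale thresholds, per-occasion unit lengths
#' (inter-threshold gap for ordinal indicators, reciprocal Bernoulli standard
#' deviation for binary ones), and the common-scale standard deviations and
#' means of the latent response variables.
#'
#' @param proportions Numeric matrix of category proportions, one row per
#'   occasion (`T x C`), or a list of per-occasion proportion vectors of a
#'   common length.
#' @param type `"auto"` (binary calculus iff `C == 2`), `"ordinal"` or
#'   `"binary"`.
#' @param unit_pair Which pair of thresholds defines the ordinal unit;
#'   default the first two.
#' @param reference Reference occasion whose unit becomes the common unit.
#' @param anchor Common-scale location of the anchored threshold (default 0).
#' @param anchor_cut Which threshold is anchored (default the first).
#'
#' @return An object of class `"scale_summary"`: a list with per-occasion
#'   `thresholds` (matrix `T x (C-1)`), `unit_lengths` (`w_t`), the common
#'   unit `w`, `sds` (`sqrt(s*_t)`), `means` (`ybar*_t`), plus the
#'   `reference`, `anchor` and `type` used.
#'
#' @examples
#' # binary response rates drifting from 16% to 84% positive
#' p <- rbind(c(pnorm(-1), pnorm(1)), c(0.5, 0.5), c(pnorm(1), pnorm(-1)))
#' scale_summary(1 - p)
#' @export
scale_summary <- function(proportions, type = c("auto", "ordinal", "binary"),
                          unit_pair = c(1L, 2L), reference = 1L, anchor = 0,
                          anchor_cut = 1L) {
  type <- match.arg(type)
  if (is.list(proportions)) {
    len <- unique(lengths(proportions))
    if (length(len) != 1L) {
      stop("all occasions must have the same number of categories")
    }
    proportions <- do.call(rbind, proportions)
  }
  if (!is.matrix(proportions) || nrow(proportions) < 2L) {
    stop("`proportions` must cover at least two occasions")
  }
  n_cat <- ncol(proportions)
  if (type == "auto") type <- if (n_cat == 2L) "binary" else "ordinal"
  if (type == "binary" && n_cat != 2L) {
    stop("the binary calculus applies only to two-category proportions")
  }
  if (type == "ordinal" && n_cat < 3L) {
    stop("the ordinal calculus needs at least three categories ",
         "(two thresholds); use type = \"binary\"")
  }

  tau <- t(apply(proportions, 1L, z_thresholds))
  if (n_cat == 2L) tau <- matrix(tau, ncol = 1L)

  w_t <- if (type == "binary") {
    binary_unit_length(proportions[, 2L])  # p = P(response is 1)
  } else {
    apply(tau, 1L, ordinal_unit_length, pair = unit_pair)
  }

  sds <- common_scale_sds(w_t, reference)
  anchor_cut <- as.integer(anchor_cut)
  if (anchor_cut < 1L || anchor_cut > ncol(tau)) stop("`anchor_cut` out of range")
  means <- common_scale_means(sds, tau[, anchor_cut], anchor)

  structure(
    list(thresholds = tau, unit_lengths = w_t, w = w_t[reference],
         sds = sds, means = means, reference = as.integer(reference),
         anchor = anchor, anchor_cut = anchor_cut, type = type),
    class = "scale_summary"
  )
}

#' @export
as.data.frame.scale_summary <- function(x, ...) {
  tau <- x$thresholds
  colnames(tau) <- paste0("tau", seq_len(ncol(tau)))
  data.frame(time = seq_along(x$unit_lengths), tau, w = x$unit_lengths,
             sqrt_s_star = x$sds, ybar_star = x$means)
}

#' @export
print.scale_summary <- function(x, digits = 3, ...) {
  cat("Common-scale summary (", x$type, " calculus, reference occasion ",
      x$reference, ", anchor ", format(x$anchor), ")\n", sep = "")
  print(round(as.data.frame(x), digits))
  invisible(x)
}
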