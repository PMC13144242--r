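#' Draw latent trajectories implied by a growth specification
#'
#' Rows are i.i.d. draws from the multivariate normal with the mean vector
#' and covariance matrix implied by the linear growth model (the composition
#' of growth factors and occasion errors is distributionally equivalent to a
#' direct draw from the implied MVN, which is what is done here).
#'
#' @param spec A [growth_spec()].
#' @param n Number of subjects.
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return `n x T` numeric matrix of latent responses.
#' @export
simulate_latent <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  m <- implied_moments(spec)
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = m$mean, Sigma = m$cov)
  if (n == 1L) x <- matrix(x, nrow = 1L)
  x
}

#' Discretise latent values by a threshold set
#'
#' Each value is mapped to the number of thresholds at or below it, so
#' categories run from 0 (below every cut) to `C - 1`; a value exactly equal
#' to a cut goes to the upper category (a probability-zero event, fixed for
#' determinism).
#'
#' @param latent Numeric matrix (or vector) of latent values.
#' @param thresholds Strictly increasing cut points (length `C - 1`).
#' @return Integer matrix (or vector) of categories in `0:(C-1)`.
#' @examples
#' categorize(c(-5, -0.1, 0, 0.3), thresholds = 0)  # 0 0 1 1
#' @export
categorize <- function(latent, thresholds) {
  if (any(diff(thresholds) <= 0) && length(thresholds) > 1L) {
    stop("`thresholds` must be strictly increasing")
  }
  k <- findInterval(latent, thresholds)
  if (is.matrix(latent)) {
    k <- matrix(as.integer(k), nrow(latent), ncol(latent))
  } else {
    k <- as.integer(k)
  }
  k
}

#' Generate a longitudinal categorical panel
#'
#' Draws latent trajectories from the growth specification and discretises
#' them with an invariant threshold set, yielding the `N x T` integer panel a
#' researcher would observe.
#'
#' @param spec A [growth_spec()].
#' @param n Number of subjects.
#' @param thresholds Cut points on the latent scale (e.g.
#'   [default_thresholds()]); invariant over occasions by construction.
#' @param seed Optional integer seed.
#' @param label Optional condition label stored with the panel.
#' @return Integer matrix of class `"catlgm_panel"` with attributes
#'   `categories`, `thresholds` and (optionally) `label`; columns are named
#'   `t1 ... tT`.
#' @examples
#' p <- simulate_panel(condition_spec("shift", "large"), n = 50,
#'                     thresholds = default_thresholds(3), seed = 1)
#' table(p[, 1])
#' @export
simulate_panel <- function(spec, n, thresholds, seed = NULL, label = NULL) {
  y <- categorize(simulate_latent(spec, n, seed), thresholds)
  colnames(y) <- paste0("t", seq_len(ncol(y)))
  structure(y, categories = length(thresholds) + 1L,
            thresholds = thresholds, label = label,
            class = c("catlgm_panel", class(y)))
}

#' @export
print.catlgm_panel <- function(x, ...) {
  cat("Categorical panel: ", nrow(x), " subjects x ", ncol(x),
      " occasions, ", attr(x, "categories"), " categories\n", sep = "")
  if (!is.null(attr(x, "label"))) cat("condition:", attr(x, "label"), "\n")
  cat("category proportions by occasion:\n")
  print(round(panel_proportions(x), 3))
  invisible(x)
}

#' Per-occasion category proportions of a panel
#'
#' @param panel Integer panel matrix.
#' @param categories Number of categories; taken from the panel attribute
#'   when present, else `max(panel) + 1`.
#' @return `T x C` matrix of proportions.
#' @export
panel_proportions <- function(panel, categories = NULL) {
  categories <- categories %||% attr(panel, "categories") %||%
    (max(panel) + 1L)
  out <- t(apply(panel, 2L, function(col) {
    tabulate(col + 1L, nbins = categories) / length(col)
  }))
  colnames(out) <- paste0("cat", 0:(categories - 1L))
  rownames(out) <- colnames(panel)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a categorical panel as delimited text
#'
#' One row per subject, columns `t1 ... tT`, integer categories. The header
#' carries the category count (and any condition label) as `#` comment
#' lines so a panel file is self-describing.
#'
#' @param panel Panel matrix as produced by [simulate_panel()].
#' @param file Path to the CSV file.
#' @return `write_panel()` returns `file` invisibly; `read_panel()` returns a
#'   `"catlgm_panel"` matrix.
#' @export
write_panel <- function(panel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  categories <- attr(panel, "categories") %||% (max(panel) + 1L)
  writeLines(sprintf("# categories: %d", categories), con)
  if (!is.null(attr(panel, "label"))) {
    writeLines(sprintf("# condition: %s", attr(panel, "label")), con)
  }
  utils::write.table(as.data.frame(unclass(panel)), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  header <- readLines(file, n = 5L)
  header <- header[startsWith(header, "#")]
  categories <- NULL
  label <- NULL
  for (h in header) {
    if (grepl("^# categories:", h)) {
      categories <- as.integer(sub("^# categories:\\s*", "", h))
    }
    if (grepl("^# condition:", h)) label <- sub("^# condition:\\s*", "", h)
  }
  y <- as.matrix(utils::read.csv(file, comment.char = "#"))
  storage.mode(y) <- "integer"
  structure(y, categories = categories %||% (max(y) + 1L),
            thresholds = NULL, label = label,
            class = c("catlgm_panel", class(y)))
}

#' Simulate panels from a growth specification
#'
#' `simulate()` method for [growth_spec()] objects: returns `nsim` panels
#' generated under the specification and a common threshold set.
#'
#' @param object A [growth_spec()].
#' @param nsim Number of panels.
#' @param seed Optional integer seed for the first panel; panel `k` uses
#'   `seed + k - 1`.
#' @param n Subjects per panel.
#' @param thresholds Cut points; default binary (0).
#' @param ... Unused.
#' @return A list of `nsim` panels (a single panel if `nsim = 1`).
#' @export
simulate.growth_spec <- function(object, nsim = 1, seed = NULL, n = 100,
                                 thresholds = 0, ...) {
  panels <- lapply(seq_len(nsim), function(k) {
    simulate_panel(object, n, thresholds,
                   seed = if (is.null(seed)) NULL else seed + k - 1L)
  })
  if (nsim == 1L) panels[[1L]] else panels
}
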