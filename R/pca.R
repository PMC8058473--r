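# PCA of accession-by-treatment mean profiles. Traits carry incompatible
# units (g, %, mg kg-1, dimensionless ratios), so columns are
# standardised to zero mean / unit SD before the eigendecomposition —
# Euclidean distances between profiles are then taken on the
# standardised scale (correlation-matrix PCA).

#' Principal component analysis of trait mean profiles
#'
#' @param means Numeric matrix, rows = accession x treatment units,
#'   columns = traits (see [mean_matrix()]).
#' @param k Number of components to keep (default
#'   `min(dim(means)) - 1`, capped at the matrix rank).
#' @return Object of class `trial_pca`: `scores` (units x k), `loadings`
#'   (traits x k, orthonormal columns), `var_explained` (fraction per
#'   component, all components), `center`, `scale`, `treatment` (row
#'   treatment labels, if present on the input).
#' @details Constant columns are dropped with a warning. The sign of
#'   each component is fixed so that its largest-magnitude loading is
#'   positive, making results reproducible across platforms.
#' @export
trial_pca <- function(means, k = NULL) {
  m <- as.matrix(means)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant trait(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (is.null(k)) k <- rank
  if (k > rank) stop("k exceeds the rank (", rank, ") of the data")
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_explained = ve, center = pc$center,
                 scale = pc$scale,
                 treatment = attr(means, "treatment")),
            class = "trial_pca")
}

#' @export
print.trial_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCA over %d units x %d traits; first %d component(s) kept\n",
              nrow(x$scores), nrow(x$loadings), k))
  cat("Variance explained:",
      paste0(round(100 * x$var_explained[seq_len(min(k, 5))], 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Confidence ellipse of 2-D scores
#'
#' Ellipse of the bivariate normal fitted to a treatment's score cloud:
#' centred on the sample mean, axes along the eigenvectors of the sample
#' covariance, semi-axis lengths \eqn{\sqrt{\lambda_i \chi^2_2(level)}}.
#'
#' @param scores_2d Two-column matrix of scores (>= 3 points).
#' @param level Coverage level (default 0.95).
#' @return Object of class `score_ellipse`: `center`, `semi_axes`
#'   (decreasing), `rotation` (radians, first axis vs x), `level`,
#'   `cov`.
#' @export
confidence_ellipse <- function(scores_2d, level = 0.95) {
  m <- as.matrix(scores_2d)
  if (nrow(m) < 3) stop("need at least 3 points")
  if (ncol(m) != 2) stop("scores must have exactly 2 columns")
  S <- stats::cov(m)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] <= ev$values[1] * 1e-12 || ev$values[1] <= 0)
    stop("degenerate covariance: points are (nearly) collinear")
  q <- stats::qchisq(level, df = 2)
  structure(list(center = colMeans(m),
                 semi_axes = sqrt(ev$values * q),
                 rotation = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                 level = level, cov = S),
            class = "score_ellipse")
}

#' Is a point inside a confidence ellipse?
#'
#' Squared Mahalanobis distance from the ellipse centre compared with
#' the chi-square(2) quantile at the ellipse's level.
#'
#' @param ellipse A [confidence_ellipse()].
#' @param points Two-column matrix (or length-2 vector).
#' @return Logical vector.
#' @export
in_ellipse <- function(ellipse, points) {
  p <- matrix(points, ncol = 2)
  d2 <- stats::mahalanobis(p, ellipse$center, ellipse$cov)
  d2 <= stats::qchisq(ellipse$level, df = 2)
}

#' Accessions outside the per-treatment confidence ellipses
#'
#' Fits one ellipse per treatment on the first two components and lists
#' the units falling outside their own treatment's ellipse.
#'
#' @param pca A [trial_pca()] with treatment labels.
#' @param level Coverage level.
#' @return Character vector of row labels outside their ellipse.
#' @export
outside_ellipses <- function(pca, level = 0.95) {
  if (is.null(pca$treatment)) stop("PCA carries no treatment labels")
  s <- pca$scores[, 1:2, drop = FALSE]
  out <- character(0)
  for (tr in unique(pca$treatment)) {
    idx <- pca$treatment == tr
    ell <- confidence_ellipse(s[idx, , drop = FALSE], level)
    out <- c(out, rownames(s)[idx][!in_ellipse(ell, s[idx, , drop = FALSE])])
  }
  out
}
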