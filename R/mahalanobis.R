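#' Squared Mahalanobis distances under a fitted location and scatter
#'
#' Evaluates `D^2(x) = (x - mu)' S^{-1} (x - mu)` for each row of `points`,
#' where `mu` and `S` are the fitted location and scatter. This is the
#' distance underlying all three niche-model variants; which estimator
#' produced the fit is immaterial to the formula.
#'
#' @param ls a `locationScatter` fit (from [estimateSample()],
#'   [estimateMCD()] or [estimateMVE()]), or any list with `location` and
#'   `scatter` elements.
#' @param points q x n numeric matrix of environment coordinates (a single
#'   location may be given as a vector).
#' @return numeric vector of q non-negative squared distances; zero exactly
#'   when a row equals the location.
#' @export
mahalanobisD2 <- function(ls, points) {
  if (is.null(ls$location) || is.null(ls$scatter)) {
    .nicheStop("shapeError", "ls must carry location and scatter")
  }
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- .asEnvMatrix(points)
  if (ncol(points) != length(ls$location)) {
    .nicheStop("shapeError", "points and fit have different dimensions")
  }
  .d2q(points, as.numeric(ls$location), as.matrix(ls$scatter))
}

#' Chi-squared niche probability
#'
#' Converts squared Mahalanobis distances to probabilities through the
#' chi-squared distribution with `dof` degrees of freedom (the number of
#' environmental dimensions). `invert = FALSE` gives the outlier
#' probability `P(chi^2_n <= D^2)`; `invert = TRUE` (the niche-modelling
#' convention) gives `P(chi^2_n > D^2)`, the probability that an
#' environment lies within the niche. For `dof = 2` these reduce to
#' `1 - exp(-D^2 / 2)` and `exp(-D^2 / 2)`.
#'
#' @param d2 numeric vector of non-negative squared distances.
#' @param dof degrees of freedom (>= 1).
#' @param invert logical; return the survival function instead of the CDF.
#' @return numeric vector of probabilities.
#' @export
nicheProbability <- function(d2, dof = 2L, invert = TRUE) {
  if (!is.numeric(d2) || any(!is.finite(d2)) || any(d2 < 0)) {
    .nicheStop("domainError", "d2 must be finite and non-negative")
  }
  if (!is.numeric(dof) || length(dof) != 1L || dof < 1) {
    .nicheStop("domainError", "dof must be a positive integer")
  }
  stats::pchisq(d2, df = dof, lower.tail = !invert)
}

#' Joint niche prediction at a set of points
#'
#' Bundles the squared distances with both probability readings
#' (`p_inside = P(chi^2_n <= D^2)`, the outlier probability, and
#' `p_niche = P(chi^2_n > D^2)`, the within-niche probability) for the rows
#' of `points`.
#'
#' @inheritParams mahalanobisD2
#' @return an object of class `nichePrediction`: a list with `d2`,
#'   `p_inside`, `p_niche` and `dof`.
#' @export
predictNiche <- function(ls, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- .asEnvMatrix(points)
  d2 <- mahalanobisD2(ls, points)
  dof <- ncol(points)
  structure(
    list(d2 = d2,
         p_inside = nicheProbability(d2, dof, invert = FALSE),
         p_niche = nicheProbability(d2, dof, invert = TRUE),
         dof = dof),
    class = "nichePrediction"
  )
}

#' @export
print.nichePrediction <- function(x, ...) {
  cat("Niche prediction at", length(x$d2), "points (dof =", x$dof, ")\n")
  cat("  p_niche:", paste(format(utils::head(x$p_niche, 5L), digits = 4),
                          collapse = ", "),
      if (length(x$p_niche) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Niche-probability surface over an environment-space grid
#'
#' Evaluates `p_niche = P(chi^2_2 > D^2)` over the Cartesian product of two
#' strictly increasing axes, returning a long-format (row-major: `axis1`
#' varies slowest) data frame suitable for contouring the elliptical niche
#' surface.
#'
#' @param ls a `locationScatter` fit.
#' @param axis1,axis2 strictly increasing numeric vectors spanning the two
#'   environmental dimensions.
#' @param file optional path; when given, the grid is also written as CSV
#'   with columns `axis1, axis2, d2, p_niche`.
#' @return data frame with columns `axis1`, `axis2`, `d2`, `p_niche`.
#' @export
predictGrid <- function(ls, axis1, axis2, file = NULL) {
  if (length(axis1) < 1L || length(axis2) < 1L) {
    .nicheStop("shapeError", "axes must be non-empty")
  }
  if (is.unsorted(axis1, strictly = TRUE) || is.unsorted(axis2, strictly = TRUE)) {
    .nicheStop("shapeError", "axes must be strictly increasing")
  }
  pts <- cbind(rep(axis1, each = length(axis2)),
               rep(axis2, times = length(axis1)))
  d2 <- mahalanobisD2(ls, pts)
  out <- data.frame(axis1 = pts[, 1], axis2 = pts[, 2], d2 = d2,
                    p_niche = nicheProbability(d2, dof = length(ls$location),
                                               invert = TRUE))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
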