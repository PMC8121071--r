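#' A finite sampling space of environments
#'
#' A sampling space is a finite weighted set of environment points standing
#' in for a region's climate space (one point per raster cell, weights the
#' relative cell frequencies). Errors are uniform draws over it; bias is
#' detection-weighted draws over it.
#'
#' @param points N x n numeric matrix of environment coordinates.
#' @param weights optional vector of N non-negative weights; normalised to
#'   sum to 1. Default uniform.
#' @return an object of class `samplingSpace` with elements `points`,
#'   `weights` and `N`.
#' @export
samplingSpace <- function(points, weights = NULL) {
  points <- .asEnvMatrix(points)
  N <- nrow(points)
  if (N < 1L) .nicheStop("shapeError", "a sampling space needs at least one point")
  if (is.null(weights)) weights <- rep(1 / N, N)
  if (length(weights) != N || any(!is.finite(weights)) || any(weights < 0)) {
    .nicheStop("domainError", "weights must be N non-negative finite values")
  }
  s <- sum(weights)
  if (s <= 0) .nicheStop("domainError", "weights must not all be zero")
  structure(list(points = points, weights = weights / s, N = N),
            class = "samplingSpace")
}

#' @export
print.samplingSpace <- function(x, ...) {
  cat("Sampling space:", x$N, "environment points,", ncol(x$points), "dimensions\n")
  rng <- apply(x$points, 2, range)
  cat("  ranges:", paste(apply(rng, 2, function(r)
    paste0("[", format(r[1], digits = 4), ", ", format(r[2], digits = 4), "]")),
    collapse = " x "), "\n")
  invisible(x)
}

#' Configuration for the synthetic climate space
#'
#' Describes the truncated bivariate-normal mixture from which
#' [generateSpace()] draws a finite climate space. The default emulates the
#' statistical structure of a temperate island climate space (mean annual
#' temperature in deg C, annual rainfall in mm) relative to the default
#' virtual niche: the bulk of the space sits in cooler, drier environments
#' well away from the niche optimum, while a smaller component overlaps the
#' niche edge — so uniform draws over the space are mostly low-detectability
#' environments, and detection-weighted draws concentrate on one side of the
#' niche.
#'
#' @param N number of environment points (>= 100); emulates raster cells.
#' @param means list of component mean vectors.
#' @param covs list of component covariance matrices.
#' @param mix mixing proportions (normalised to sum to 1).
#' @param bounds list of length-2 ranges, one per dimension; draws outside
#'   are rejected.
#' @return a list of class `spaceConfig`.
#' @export
spaceConfig <- function(N = 2000L,
                        means = list(c(4.5, 900), c(7.0, 1500)),
                        covs = list(matrix(c(6, 900, 900, 360000), 2, 2),
                                    matrix(c(2.5, 0, 0, 250000), 2, 2)),
                        mix = c(0.8, 0.2),
                        bounds = list(c(-2, 16), c(50, 6000))) {
  if (!is.numeric(N) || N < 100) {
    .nicheStop("domainError", "a generated space needs N >= 100 points")
  }
  stopifnot(length(means) == length(covs), length(means) == length(mix))
  if (any(mix < 0) || sum(mix) <= 0) {
    .nicheStop("domainError", "mixing proportions must be non-negative")
  }
  for (C in covs) if (!.isPD(as.matrix(C))) {
    .nicheStop("invalidParameterError", "each component covariance must be positive definite")
  }
  structure(list(N = as.integer(N), means = means,
                 covs = lapply(covs, as.matrix), mix = mix / sum(mix),
                 bounds = bounds),
            class = "spaceConfig")
}

#' Generate a synthetic sampling space
#'
#' Draws `config$N` environment points from the truncated mixture described
#' by a [spaceConfig()], with uniform weights `1/N`. Deterministic given
#' `seed`.
#'
#' @param config a `spaceConfig`.
#' @param seed integer seed (or `NULL` for the ambient RNG stream).
#' @return a [samplingSpace()].
#' @export
generateSpace <- function(config = spaceConfig(), seed = NULL) {
  stopifnot(inherits(config, "spaceConfig"))
  n <- length(config$means[[1]])
  inBounds <- function(P) {
    ok <- rep(TRUE, nrow(P))
    for (j in seq_len(n)) {
      ok <- ok & P[, j] >= config$bounds[[j]][1] & P[, j] <= config$bounds[[j]][2]
    }
    ok
  }
  .withSeed(seed, {
    acc <- matrix(numeric(0), 0, n)
    attempts <- 0
    while (nrow(acc) < config$N) {
      need <- config$N - nrow(acc)
      batch <- max(need * 2L, 200L)
      comp <- sample.int(length(config$mix), batch, replace = TRUE,
                         prob = config$mix)
      P <- matrix(NA_real_, batch, n)
      for (ci in seq_along(config$mix)) {
        rows <- which(comp == ci)
        if (length(rows)) {
          P[rows, ] <- .rmvnorm(length(rows), config$means[[ci]],
                                config$covs[[ci]])
        }
      }
      P <- P[inBounds(P), , drop = FALSE]
      acc <- rbind(acc, P)
      attempts <- attempts + batch
      if (attempts > 1e3 * config$N && nrow(acc) == 0) {
        .nicheStop("emptySpaceError", "bounds exclude essentially all mixture mass")
      }
      if (attempts > 1e4 * config$N) {
        .nicheStop("emptySpaceError", "bounds exclude almost all mixture mass")
      }
    }
    acc <- acc[seq_len(config$N), , drop = FALSE]
    colnames(acc) <- c("temperature", "rainfall")[seq_len(n)]
    samplingSpace(acc)
  })
}

#' Load a sampling space from CSV
#'
#' Reads a headed CSV with two numeric environment columns (temperature,
#' rainfall) and an optional `weight` column — the route for substituting a
#' real climate-space extraction for the synthetic default.
#'
#' @param path CSV file path.
#' @return a [samplingSpace()].
#' @export
readSamplingSpace <- function(path) {
  x <- utils::read.csv(path, header = TRUE)
  w <- NULL
  if ("weight" %in% names(x)) {
    w <- x$weight
    x <- x[setdiff(names(x), "weight")]
  }
  samplingSpace(as.matrix(x[vapply(x, is.numeric, logical(1))]), weights = w)
}

#' Uniform (error) draws from a sampling space
#'
#' Samples `count` rows from `space$points` with replacement, with
#' probability proportional to the weights — the error model: a record that
#' is a random location within the region, unrelated to the niche.
#'
#' @param space a [samplingSpace()].
#' @param count number of draws (>= 0).
#' @param seed integer seed, or `NULL` for the ambient RNG stream.
#' @return count x n matrix of environment coordinates.
#' @export
drawUniform <- function(space, count, seed = NULL) {
  stopifnot(inherits(space, "samplingSpace"), count >= 0)
  if (count == 0) {
    return(space$points[integer(0), , drop = FALSE])
  }
  .withSeed(seed, {
    idx <- sample.int(space$N, size = count, replace = TRUE,
                      prob = space$weights)
    space$points[idx, , drop = FALSE]
  })
}

#' Detection-weighted (bias) draws from a sampling space
#'
#' Rejection sampling of the bias model: points are drawn uniformly from
#' the space and accepted with the presence-and-detection probability
#' `P_d(lambda_F(x))`, so accepted records concentrate where the region's
#' climate space overlaps the fundamental niche.
#'
#' @param space a [samplingSpace()].
#' @param params a [nicheParams()] defining `lambda_F`.
#' @param count number of accepted points required.
#' @param seed integer seed, or `NULL` for the ambient RNG stream.
#' @param max_attempts iteration cap on candidate draws; exceeded means the
#'   space offers essentially no detectable environments.
#' @return count x n matrix of environment coordinates (all rows members of
#'   `space$points`).
#' @export
drawBiased <- function(space, params, count, seed = NULL, max_attempts = 1e6) {
  stopifnot(inherits(space, "samplingSpace"), inherits(params, "nicheParams"),
            count >= 0)
  if (count == 0) {
    return(space$points[integer(0), , drop = FALSE])
  }
  pd <- detectionProbability(nicheGrowthRate(params, space$points))
  .withSeed(seed, {
    acc <- integer(0)
    attempts <- 0
    while (length(acc) < count) {
      if (attempts >= max_attempts) {
        .nicheStop("biasInfeasibleError", sprintf(
          "could not accept %d detection-weighted points in %d attempts",
          count, as.integer(attempts)))
      }
      batch <- min(max(2L * (count - length(acc)), 100L),
                   max_attempts - attempts)
      idx <- sample.int(space$N, size = batch, replace = TRUE,
                        prob = space$weights)
      keep <- stats::runif(batch) < pd[idx]
      acc <- c(acc, idx[keep])
      attempts <- attempts + batch
    }
    space$points[acc[seq_len(count)], , drop = FALSE]
  })
}
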