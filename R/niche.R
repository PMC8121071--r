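#' Fundamental niche parameters of a virtual species
#'
#' Defines an elliptical Gaussian fundamental niche in environment space.
#' The niche is parameterised by the maximum finite rate of increase
#' `lambda_max` attained at the niche optimum `mu`, and a variance-covariance
#' matrix `sigma` giving the size and orientation of the niche in each
#' environmental dimension. Defaults describe a virtual species in a
#' two-dimensional climate space of mean annual temperature (deg C) and
#' annual rainfall (mm).
#'
#' @param lambda_max positive scalar; maximum finite rate of increase at the
#'   niche optimum (unitless).
#' @param mu numeric vector; optimal environmental conditions, one entry per
#'   environmental dimension.
#' @param sigma symmetric positive-definite matrix; niche size/orientation.
#'
#' @return An object of class `nicheParams` with elements `lambda_max`,
#'   `mu`, `sigma` and `n` (the number of environmental dimensions).
#'
#' @examples
#' np <- nicheParams()
#' nicheGrowthRate(np, np$mu)  # 2.5 at the optimum
#' @export
nicheParams <- function(lambda_max = 2.5,
                        mu = c(temperature = 7.5, rainfall = 1800),
                        sigma = matrix(c(2, -950, -950, 800000), 2, 2)) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      !is.finite(lambda_max) || lambda_max <= 0) {
    .nicheStop("invalidParameterError", "lambda_max must be a positive finite scalar")
  }
  if (!is.numeric(mu) || length(mu) < 1L || any(!is.finite(mu))) {
    .nicheStop("invalidParameterError", "mu must be a finite numeric vector")
  }
  sigma <- as.matrix(sigma)
  n <- length(mu)
  if (!all(dim(sigma) == n)) {
    .nicheStop("shapeError", "sigma must be n x n with n = length(mu)")
  }
  if (!isSymmetric(unname(sigma), tol = 1e-8)) {
    .nicheStop("invalidParameterError", "sigma must be symmetric")
  }
  if (!.isPD(sigma)) {
    .nicheStop("invalidParameterError", "sigma must be positive definite")
  }
  structure(
    list(lambda_max = as.numeric(lambda_max), mu = mu,
         sigma = unname(sigma), n = n),
    class = "nicheParams"
  )
}

#' @export
print.nicheParams <- function(x, ...) {
  cat("Fundamental niche (elliptical Gaussian), n =", x$n, "\n")
  cat("  lambda_max:", format(x$lambda_max), "\n")
  cat("  mu:        ", paste(format(x$mu), collapse = ", "), "\n")
  cat("  sigma:\n")
  print(x$sigma)
  invisible(x)
}

#' Finite rate of increase over environment space
#'
#' Evaluates the fundamental-niche growth surface
#' \deqn{\lambda_F(x) = \lambda_{max} \exp\{-\tfrac12 (x-\mu)^T \Sigma^{-1} (x-\mu)\}}
#' at each row of `points`. The quadratic form is computed through a
#' Cholesky solve rather than an explicit matrix inverse.
#'
#' @param params a [nicheParams()] object.
#' @param points numeric matrix with one row per environment location and
#'   `params$n` columns, or a single location as a vector.
#' @return numeric vector of growth rates in `(0, lambda_max]`.
#' @export
nicheGrowthRate <- function(params, points) {
  stopifnot(inherits(params, "nicheParams"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- .asEnvMatrix(points)
  if (ncol(points) != params$n) {
    .nicheStop("shapeError", sprintf(
      "points have %d columns; niche has %d dimensions", ncol(points), params$n))
  }
  d2 <- .d2q(points, as.numeric(params$mu), params$sigma,
             errclass = "invalidParameterError")
  params$lambda_max * exp(-d2 / 2)
}

#' Probability of presence-and-detection
#'
#' Logistic detection filter linking the finite rate of increase to the
#' probability that sampling an environment yields a present-and-detected
#' occurrence: `P_d = 1 / (1 + exp(-10 (lambda_f - 0.5)))`. The steepness
#' and midpoint are fixed so that `P_d` is near 0 where the population
#' cannot persist (`lambda_f` near 0) and near 1 where `lambda_f >= 1`.
#'
#' @param lambda_f numeric vector of non-negative growth rates.
#' @return numeric vector of probabilities in (0, 1).
#' @export
detectionProbability <- function(lambda_f) {
  if (!is.numeric(lambda_f) || any(!is.finite(lambda_f))) {
    .nicheStop("domainError", "lambda_f must be finite numeric")
  }
  if (any(lambda_f < 0)) {
    .nicheStop("domainError", "lambda_f must be non-negative")
  }
  stats::plogis(10 * (lambda_f - 0.5))
}

#' Read/write niche parameters as JSON
#'
#' Serialises a [nicheParams()] object to a plain JSON config with keys
#' `lambda_max`, `mu`, `sigma` (row-major matrix), or reads one back.
#'
#' @param params a `nicheParams` object.
#' @param path file path.
#' @return `readNicheParams` returns a `nicheParams` object;
#'   `writeNicheParams` returns `path` invisibly.
#' @export
writeNicheParams <- function(params, path) {
  stopifnot(inherits(params, "nicheParams"))
  jsonlite::write_json(
    list(lambda_max = params$lambda_max,
         mu = as.numeric(params$mu),
         sigma = params$sigma),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeNicheParams
#' @export
readNicheParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nicheParams(lambda_max = x$lambda_max, mu = as.numeric(x$mu),
              sigma = as.matrix(x$sigma))
}
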