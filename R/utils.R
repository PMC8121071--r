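# Internal helpers shared across modules.

# Classed error so callers can condition on failure mode.
.nicheStop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nicheD2Error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL means "use the
# ambient stream" (no seeding, no restore).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Splittable child-seed scheme: fold integer components into [0, 2^31 - 2]
# with a 69069 multiplicative-congruential hash. All arithmetic stays below
# 2^53 so it is exact in doubles, and the result fits a 32-bit R integer.
.childSeed <- function(seed, ...) {
  p <- 2147483647
  h <- as.numeric(seed) %% p
  for (v in c(...)) {
    h <- (h * 69069 + as.numeric(v) + 1) %% p
  }
  as.integer(h)
}

# Squared Mahalanobis distances of the rows of X from `location` under
# `scatter`, via a Cholesky solve (no explicit inverse). Errors with the
# supplied condition class when scatter is not (numerically) positive
# definite.
.d2q <- function(X, location, scatter, errclass = "degenerateModelError") {
  R <- tryCatch(chol(scatter), error = function(e) NULL)
  if (is.null(R) || any(diag(R) <= sqrt(.Machine$double.eps) * max(diag(R)))) {
    .nicheStop(errclass, "scatter matrix is not positive definite")
  }
  Z <- backsolve(R, t(X) - location, transpose = TRUE)
  colSums(Z * Z)
}

# TRUE when `S` admits a Cholesky factor with healthy diagonal.
.isPD <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  !is.null(R) && all(diag(R) > sqrt(.Machine$double.eps) * max(diag(R)))
}

# Coerce estimator input to a plain numeric matrix: accepts a matrix, a
# data frame, an occurrenceSample, or a path to a headed CSV of numeric
# environment columns.
.asEnvMatrix <- function(X) {
  if (inherits(X, "occurrenceSample")) X <- X$X
  if (is.character(X) && length(X) == 1L) {
    X <- utils::read.csv(X, header = TRUE)
    X <- X[vapply(X, is.numeric, logical(1))]
  }
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    .nicheStop("shapeError", "expected a numeric matrix of environment coordinates")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    .nicheStop("shapeError", "environment coordinates must be finite")
  }
  X
}

# Nearest-integer rounding, halves away from zero (round() in R rounds
# halves to even, which would break the exact m = 100 contamination grids).
.roundHalfUp <- function(x) floor(x + 0.5)

# Multivariate normal draws (thin wrapper so the sampling routine is in one
# place; MASS::mvrnorm is the canonical generator).
.rmvnorm <- function(n, mu, sigma) {
  MASS::mvrnorm(n = n, mu = mu, Sigma = sigma)
}
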