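#' Estimator configuration
#'
#' Tuning knobs shared by the robust estimators [estimateMCD()] and
#' [estimateMVE()].
#'
#' @param k subset proportion in (0.5, 1], giving subset size
#'   `h = floor(k * m)`; `NULL` uses the standard maximal-robustness choice
#'   `h = floor((m + n + 1) / 2)`.
#' @param n_trials number of random elemental (n+1)-point starts in fast
#'   mode.
#' @param max_csteps cap on concentration steps per start (convergence is
#'   typically reached in well under 10).
#' @param exhaustive logical; enumerate all candidate subsets instead of
#'   random starts. Permitted only when the enumeration has at most 10^6
#'   subsets.
#' @param rescale logical; apply the chi-squared consistency rescaling so
#'   that the robust scatter is comparable to a covariance under
#'   multivariate normality (see Details in [estimateMCD()]).
#' @param reweight logical; apply the standard one-step reweighting after
#'   the raw robust fit (see Details in [estimateMCD()]). Skipped at
#'   `h = m`, where the estimator is the classical one by construction.
#' @param seed integer seed for the random starts, or `NULL` to use the
#'   ambient RNG stream.
#' @return a list of class `estimatorConfig`.
#' @export
estimatorConfig <- function(k = NULL, n_trials = 500L, max_csteps = 100L,
                            exhaustive = FALSE, rescale = TRUE,
                            reweight = TRUE, seed = NULL) {
  if (!is.null(k)) {
    if (!is.numeric(k) || length(k) != 1L || k <= 0.5 || k > 1) {
      .nicheStop("domainError", "k must lie in (0.5, 1]")
    }
  }
  if (!is.numeric(n_trials) || n_trials < 1) {
    .nicheStop("domainError", "n_trials must be >= 1")
  }
  if (!is.numeric(max_csteps) || max_csteps < 1) {
    .nicheStop("domainError", "max_csteps must be >= 1")
  }
  structure(
    list(k = k, n_trials = as.integer(n_trials),
         max_csteps = as.integer(max_csteps),
         exhaustive = isTRUE(exhaustive), rescale = isTRUE(rescale),
         reweight = isTRUE(reweight),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "estimatorConfig"
  )
}

#' Subset size for the robust estimators
#'
#' Returns the number of points `h` retained by the MCD/MVE estimators:
#' `floor(k * m)` when a proportion `k` is given, otherwise the standard
#' maximal-robustness choice `floor((m + n + 1) / 2)`. The result is clamped
#' to `[n + 1, m]` so the subset covariance is estimable.
#'
#' @param m sample size.
#' @param n number of environmental dimensions.
#' @param k subset proportion in (0.5, 1], or `NULL` for the standard
#'   choice.
#' @return integer subset size `h`.
#' @examples
#' subsetSize(10, 2)        # 6
#' subsetSize(160, 2)       # 81
#' subsetSize(50, 2, k = 1) # 50
#' @export
subsetSize <- function(m, n, k = NULL) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < n + 1L) {
    .nicheStop("infeasibleSubsetError", sprintf(
      "cannot form a non-degenerate subset: m = %d < n + 1 = %d", m, n + 1L))
  }
  h <- if (is.null(k)) {
    (m + n + 1L) %/% 2L
  } else {
    if (!is.numeric(k) || length(k) != 1L || k <= 0.5 || k > 1) {
      .nicheStop("domainError", "k must lie in (0.5, 1]")
    }
    as.integer(floor(k * m))
  }
  min(max(h, n + 1L), m)
}

# Constructor + validity for a fitted location/scatter.
.locationScatter <- function(location, scatter, method, h = NULL,
                             retained = NULL, objective = NULL) {
  location <- as.numeric(location)
  scatter <- unname(as.matrix(scatter))
  n <- length(location)
  stopifnot(all(dim(scatter) == n))
  if (!isSymmetric(scatter, tol = 1e-8)) {
    .nicheStop("degenerateModelError", "scatter must be symmetric")
  }
  scatter <- (scatter + t(scatter)) / 2
  if (!.isPD(scatter)) {
    .nicheStop("degenerateSampleError", "scatter estimate is singular")
  }
  if (!is.null(h)) {
    h <- as.integer(h)
    if (h < n + 1L) .nicheStop("infeasibleSubsetError", "h < n + 1")
  }
  if (!is.null(retained)) {
    retained <- sort.int(as.integer(retained))
    stopifnot(!anyDuplicated(retained))
  }
  structure(
    list(location = location, scatter = scatter,
         method = match.arg(method, c("sample", "mcd", "mve")),
         h = h, retained = retained, objective = objective),
    class = "locationScatter"
  )
}

#' @export
print.locationScatter <- function(x, ...) {
  cat("Multivariate location and scatter (", x$method, ")\n", sep = "")
  cat("  location:", paste(format(x$location), collapse = ", "), "\n")
  if (!is.null(x$h)) cat("  h:", x$h, "\n")
  if (!is.null(x$objective)) cat("  objective:", format(x$objective), "\n")
  cat("  scatter:\n")
  print(x$scatter)
  invisible(x)
}

#' Sample mean and variance-covariance estimator
#'
#' The classical multivariate location and scatter: column means and the
#' sample variance-covariance matrix (denominator `m - 1`).
#'
#' @param X an m x n numeric matrix of environment coordinates (also
#'   accepts a data frame, an [occurrenceSample], or a path to a headed
#'   numeric CSV).
#' @return a `locationScatter` object with `method = "sample"`.
#' @export
estimateSample <- function(X) {
  X <- .asEnvMatrix(X)
  m <- nrow(X); n <- ncol(X)
  if (m < n + 1L) {
    .nicheStop("degenerateSampleError", sprintf(
      "need at least n + 1 = %d points, got %d", n + 1L, m))
  }
  S <- stats::cov(X)
  if (!.isPD(S)) {
    .nicheStop("degenerateSampleError",
               "sample covariance is singular (collinear or duplicated points)")
  }
  .locationScatter(colMeans(X), S, "sample")
}

# One concentration (C-step) pass to convergence from an initial subset.
# Each step computes D^2 of all m points under the current estimate, keeps
# the h smallest (ties broken by lowest row index), and re-estimates; the
# covariance determinant is non-increasing along the sequence. Returns NULL
# if a step hits a singular covariance. `path` records the determinant after
# every h-subset re-estimation.
.concentrate <- function(X, idx, h, max_csteps) {
  m <- nrow(X)
  loc <- colMeans(X[idx, , drop = FALSE])
  S <- stats::cov(X[idx, , drop = FALSE])
  dt <- Inf
  path <- numeric(0)
  for (i in seq_len(max_csteps)) {
    d2 <- tryCatch(.d2q(X, loc, S), error = function(e) NULL)
    if (is.null(d2)) return(NULL)
    idx <- sort.int(order(d2, seq_len(m))[seq_len(h)])
    loc <- colMeans(X[idx, , drop = FALSE])
    S <- stats::cov(X[idx, , drop = FALSE])
    dt2 <- det(S)
    path <- c(path, dt2)
    if (is.finite(dt) && dt2 >= dt * (1 - 1e-12)) {
      dt <- min(dt, dt2)
      break
    }
    dt <- dt2
  }
  if (!.isPD(S)) return(NULL)
  list(idx = idx, location = loc, scatter = S, det = dt, path = path)
}

# One-step reweighting from a retained h-subset: the subset covariance is
# inflated by the small-sample factor (1 + 15/(m - n))^2, all m points get
# squared distances under it, and the classical mean/covariance of the
# points below the cutoff
#   qchisq(0.975, n) * quantile(d2, h/m) / qchisq(h/m, n)
# (an empirically consistency-corrected 97.5% chi-squared fence) are
# returned. Improves the finite-sample efficiency of the raw subset
# estimates substantially while keeping their outlier resistance. Returns
# NULL when the reweighted covariance is degenerate.
.reweight <- function(X, idx, h) {
  m <- nrow(X); n <- ncol(X)
  c0 <- colMeans(X[idx, , drop = FALSE])
  C0 <- stats::cov(X[idx, , drop = FALSE]) * (1 + 15 / (m - n))^2
  d2 <- tryCatch(.d2q(X, c0, C0), error = function(e) NULL)
  if (is.null(d2)) return(NULL)
  cut <- stats::qchisq(0.975, n) *
    stats::quantile(d2, h / m, type = 7, names = FALSE) /
    stats::qchisq(h / m, n)
  keep <- which(d2 < cut)
  if (length(keep) < n + 1L) return(NULL)
  S <- stats::cov(X[keep, , drop = FALSE])
  if (!.isPD(S)) return(NULL)
  list(location = colMeans(X[keep, , drop = FALSE]), scatter = S)
}

# Random elemental start: n+1 rows, extended one random row at a time while
# the subset covariance is singular (FAST-MCD convention).
.elementalStart <- function(X, n) {
  m <- nrow(X)
  idx <- sample.int(m, n + 1L)
  while (length(idx) < m) {
    S <- stats::cov(X[idx, , drop = FALSE])
    if (.isPD(S)) return(idx)
    idx <- c(idx, sample(setdiff(seq_len(m), idx), 1L))
  }
  if (.isPD(stats::cov(X))) seq_len(m) else NULL
}

#' Minimum covariance determinant (MCD) estimator
#'
#' Finds the size-`h` subset of the sample whose covariance matrix has the
#' smallest determinant, and returns that subset's mean and covariance
#' (denominator `h - 1`). Fast mode runs `n_trials` random elemental
#' (n+1)-point starts, each refined by concentration steps until the
#' determinant stops decreasing; exhaustive mode enumerates every
#' `choose(m, h)` subset (permitted up to 10^6 subsets) and is intended as a
#' small-sample oracle.
#'
#' When `config$reweight` is `TRUE` (the default) the raw subset estimate is
#' refined by the standard one-step reweighting: the subset covariance is
#' inflated by `(1 + 15/(m - n))^2`, every point gets a squared distance
#' under it, and the classical mean and covariance of the points inside an
#' empirically consistency-corrected 97.5% chi-squared fence are returned.
#' This recovers most of the classical estimator's finite-sample efficiency
#' while keeping the raw estimator's resistance to outliers; it is skipped
#' at `h = m`. With `reweight = FALSE` the raw subset mean/covariance is
#' returned, multiplied (when `config$rescale`) by the consistency factor
#' `median(D^2 over retained points) / qchisq(0.5, n)` so that under
#' multivariate normality its Mahalanobis distances follow the chi-squared
#' calibration used for niche probabilities. `objective` always records the
#' raw subset determinant.
#'
#' The estimator requires `m >= 5 n`; with the two-dimensional climate
#' space this puts the smallest analysable sample at `m = 10`.
#'
#' @inheritParams estimateSample
#' @param config an [estimatorConfig()].
#' @return a `locationScatter` object with `method = "mcd"`, the subset size
#'   `h`, the retained row indices, and the determinant objective.
#' @export
estimateMCD <- function(X, config = estimatorConfig()) {
  stopifnot(inherits(config, "estimatorConfig"))
  X <- .asEnvMatrix(X)
  m <- nrow(X); n <- ncol(X)
  if (m < 5L * n) {
    .nicheStop("sampleSizeError", sprintf(
      "MCD requires m >= 5 n: m = %d, n = %d", m, n))
  }
  h <- subsetSize(m, n, config$k)

  if (h >= m) {
    # the only size-m subset is the full sample
    loc <- colMeans(X)
    S <- stats::cov(X)
    if (!.isPD(S)) .nicheStop("degenerateSampleError", "sample covariance is singular")
    best <- list(idx = seq_len(m), location = loc, scatter = S, det = det(S))
  } else if (config$exhaustive) {
    if (choose(m, h) > 1e6) {
      .nicheStop("sizeError", sprintf(
        "exhaustive MCD refused: choose(%d, %d) > 1e6", m, h))
    }
    subsets <- utils::combn(m, h)
    best <- NULL
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      S <- stats::cov(X[idx, , drop = FALSE])
      if (!.isPD(S)) next
      dt <- det(S)
      if (is.null(best) || dt < best$det) {
        best <- list(idx = idx, location = colMeans(X[idx, , drop = FALSE]),
                     scatter = S, det = dt)
      }
    }
    if (is.null(best)) .nicheStop("degenerateSampleError", "every candidate subset is singular")
  } else {
    best <- .withSeed(config$seed, {
      b <- NULL
      for (t in seq_len(config$n_trials)) {
        idx0 <- .elementalStart(X, n)
        if (is.null(idx0)) next
        fit <- .concentrate(X, idx0, h, config$max_csteps)
        if (is.null(fit)) next
        if (is.null(b) || fit$det < b$det) b <- fit
      }
      b
    })
    if (is.null(best)) .nicheStop("degenerateSampleError", "every candidate subset is singular")
  }

  location <- best$location
  scatter <- best$scatter
  reweighted <- FALSE
  if (config$reweight && h < m) {
    rw <- .reweight(X, best$idx, h)
    if (!is.null(rw)) {
      location <- rw$location
      scatter <- rw$scatter
      reweighted <- TRUE
    }
  }
  if (!reweighted && config$rescale) {
    d2 <- .d2q(X[best$idx, , drop = FALSE], best$location, best$scatter)
    scatter <- best$scatter * stats::median(d2) / stats::qchisq(0.5, df = n)
  }
  .locationScatter(location, scatter, "mcd", h = h,
                   retained = best$idx, objective = best$det)
}

#' Minimum volume ellipsoid (MVE) estimator
#'
#' Approximates the smallest-volume ellipsoid covering `h` sample points by
#' elemental-subset resampling: for each (n+1)-point subset with mean `c`
#' and covariance `C`, the ellipsoid `{x : (x - c)' C^{-1} (x - c) <= lambda}`
#' with `lambda` the h-th smallest squared distance covers exactly `h`
#' points, and its volume is proportional to `sqrt(det(C) * lambda^n)`. The
#' candidate minimising `det(C) * lambda^n` wins; its location is `c` and
#' its scatter `lambda * C`. Exhaustive mode enumerates all
#' `choose(m, n + 1)` elemental subsets (up to 10^6).
#'
#' When `config$reweight` is `TRUE` (the default) the `h` covered points
#' seed the same one-step reweighting as in [estimateMCD()]; the returned
#' location/scatter are then the classical mean/covariance of the points
#' inside the consistency-corrected chi-squared fence. With
#' `reweight = FALSE` and `config$rescale` the raw scatter `lambda * C` is
#' divided by `qchisq(h / m, n)` so the ellipsoid boundary sits at the
#' chi-squared quantile matching the covered fraction; this rescaling is
#' undefined at `h = m` (the quantile is infinite), where it must be
#' switched off.
#'
#' @inheritParams estimateMCD
#' @return a `locationScatter` object with `method = "mve"`, the subset size
#'   `h`, the indices of the `h` covered points, and the volume objective
#'   `det(C) * lambda^n`.
#' @export
estimateMVE <- function(X, config = estimatorConfig()) {
  stopifnot(inherits(config, "estimatorConfig"))
  X <- .asEnvMatrix(X)
  m <- nrow(X); n <- ncol(X)
  h <- subsetSize(m, n, config$k)
  if (config$rescale && h == m) {
    .nicheStop("domainError",
               "MVE consistency rescaling is undefined at h = m (qchisq(1, n) is infinite); set rescale = FALSE")
  }

  evalCandidate <- function(idx) {
    c0 <- colMeans(X[idx, , drop = FALSE])
    C0 <- stats::cov(X[idx, , drop = FALSE])
    d2 <- tryCatch(.d2q(X, c0, C0), error = function(e) NULL)
    if (is.null(d2)) return(NULL)
    ord <- order(d2, seq_len(m))
    lam <- d2[ord[h]]
    if (lam <= 0) return(NULL)
    list(location = c0, C = C0, lam = lam, obj = det(C0) * lam^n,
         retained = ord[seq_len(h)])
  }

  best <- if (config$exhaustive) {
    if (choose(m, n + 1L) > 1e6) {
      .nicheStop("sizeError", sprintf(
        "exhaustive MVE refused: choose(%d, %d) > 1e6", m, n + 1L))
    }
    subsets <- utils::combn(m, n + 1L)
    b <- NULL
    for (j in seq_len(ncol(subsets))) {
      cand <- evalCandidate(subsets[, j])
      if (!is.null(cand) && (is.null(b) || cand$obj < b$obj)) b <- cand
    }
    b
  } else {
    .withSeed(config$seed, {
      b <- NULL
      for (t in seq_len(config$n_trials)) {
        cand <- evalCandidate(sample.int(m, n + 1L))
        if (!is.null(cand) && (is.null(b) || cand$obj < b$obj)) b <- cand
      }
      b
    })
  }
  if (is.null(best)) .nicheStop("degenerateSampleError", "every elemental subset is singular")

  location <- best$location
  scatter <- best$lam * best$C
  reweighted <- FALSE
  if (config$reweight && h < m) {
    rw <- .reweight(X, best$retained, h)
    if (!is.null(rw)) {
      location <- rw$location
      scatter <- rw$scatter
      reweighted <- TRUE
    }
  }
  if (!reweighted && config$rescale) {
    scatter <- scatter / stats::qchisq(h / m, df = n)
  }
  .locationScatter(location, scatter, "mve", h = h,
                   retained = best$retained, objective = best$obj)
}

#' Read an environment matrix from CSV
#'
#' Reads a headed CSV of numeric environment columns (e.g. temperature,
#' rainfall) into the plain matrix the estimators accept.
#'
#' @param path CSV file path.
#' @return numeric matrix.
#' @export
readEnvironmentCSV <- function(path) .asEnvMatrix(path)

#' Read/write a fitted location and scatter as JSON
#'
#' Serialises the fit as keys `location`, `scatter` (row-major), `method`,
#' `h`, `objective`.
#'
#' @param ls a `locationScatter` object.
#' @param path file path.
#' @return `readLocationScatter` returns a `locationScatter`;
#'   `writeLocationScatter` returns `path` invisibly.
#' @export
writeLocationScatter <- function(ls, path) {
  stopifnot(inherits(ls, "locationScatter"))
  jsonlite::write_json(
    list(location = ls$location, scatter = ls$scatter, method = ls$method,
         h = ls$h, objective = ls$objective),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeLocationScatter
#' @export
readLocationScatter <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nullable <- function(v) if (length(v)) v else NULL
  .locationScatter(as.numeric(x$location), as.matrix(x$scatter), x$method,
                   h = nullable(x$h), objective = nullable(x$objective))
}
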