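# Independent oracles and fixtures. These deliberately avoid the package's
# internal code paths: quadratic forms use an explicit matrix inverse, and
# the robust-estimator oracles are plain brute-force enumerations.

# Quadratic form via explicit inverse (oracle for the Cholesky-solve path).
oracleD2 <- function(X, mu, S) {
  Sinv <- solve(S)
  apply(X, 1, function(x) as.numeric(t(x - mu) %*% Sinv %*% (x - mu)))
}

# Exhaustive MCD: smallest covariance determinant over all size-h subsets.
oracleMCDObjective <- function(X, h) {
  m <- nrow(X)
  subsets <- combn(m, h)
  dets <- apply(subsets, 2, function(idx) {
    S <- cov(X[idx, , drop = FALSE])
    d <- det(S)
    if (d <= 0) Inf else d
  })
  min(dets)
}

# Exhaustive MVE over elemental subsets: det(C) * lambda^n with lambda the
# h-th smallest squared distance under each elemental mean/covariance.
oracleMVEObjective <- function(X, h) {
  m <- nrow(X); n <- ncol(X)
  subsets <- combn(m, n + 1)
  objs <- apply(subsets, 2, function(idx) {
    c0 <- colMeans(X[idx, , drop = FALSE])
    C0 <- cov(X[idx, , drop = FALSE])
    if (det(C0) <= 0) return(Inf)
    d <- oracleD2(X, c0, C0)
    lam <- sort(d)[h]
    if (lam <= 0) return(Inf)
    det(C0) * lam^n
  })
  min(objs)
}

# 12-point fixture: a tight 10-point cluster plus two gross outliers.
clusterFixture <- function() {
  set.seed(4712)
  X <- matrix(rnorm(20, sd = 1), 10, 2)
  rbind(X, c(10, 10), c(12, -8))
}

# 21-point fixture: 20-point cluster plus one far outlier (last row).
outlierFixture <- function() {
  set.seed(915)
  rbind(matrix(rnorm(40, sd = 1), 20, 2), c(25, -30))
}
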