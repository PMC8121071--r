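test_that("subset size follows the floor rules and clamps to feasibility", {
  expect_identical(subsetSize(10, 2), 6L)
  expect_identical(subsetSize(160, 2), 81L)
  expect_identical(subsetSize(50, 2, k = 1.0), 50L)
  expect_identical(subsetSize(10, 2, k = 0.55), 5L)   # floor(0.55 * 10)
  expect_identical(subsetSize(100, 2, k = 0.55), 55L)
  # clamped into [n + 1, m]
  expect_identical(subsetSize(4, 2, k = 0.6), 3L)
  expect_error(subsetSize(2, 2), class = "infeasibleSubsetError")
  expect_error(subsetSize(10, 2, k = 0.4), class = "domainError")
  expect_error(subsetSize(10, 2, k = 1.2), class = "domainError")
})

test_that("sample estimator reproduces hand-computed mean and covariance", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  fit <- estimateSample(X)
  expect_equal(fit$location, c(1, 1))
  expect_equal(fit$scatter, matrix(c(4 / 3, 0, 0, 4 / 3), 2, 2))
  expect_identical(fit$method, "sample")
  expect_null(fit$h)
  expect_error(estimateSample(rbind(c(0, 0), c(2, 2))),
               class = "degenerateSampleError")
  expect_error(estimateSample(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "degenerateSampleError")  # collinear
})

test_that("sample estimator recovers the true mean at large m", {
  np <- nicheParams()
  X <- nicheD2:::.withSeed(99, MASS::mvrnorm(1000, np$mu, np$sigma))
  fit <- estimateSample(X)
  se <- sqrt(diag(np$sigma) / 1000)
  expect_true(all(abs(fit$location - as.numeric(np$mu)) < 3 * se))
})

test_that("MCD at h = m with rescaling off reproduces the sample estimator", {
  np <- nicheParams()
  s <- sampleIdealised(np, 40, seed = 3)
  cfg <- estimatorConfig(k = 1.0, rescale = FALSE, seed = 1)
  fit_mcd <- estimateMCD(s, cfg)
  fit_s <- estimateSample(s)
  expect_identical(fit_mcd$location, fit_s$location)
  expect_equal(fit_mcd$scatter, fit_s$scatter, tolerance = 1e-10)
  expect_identical(fit_mcd$h, 40L)
})

test_that("fast-mode MCD attains the exhaustive optimum on a small fixture", {
  X <- clusterFixture()  # m = 12, two gross outliers
  h <- 7L
  fit_ex <- estimateMCD(X, estimatorConfig(k = 7 / 12 + 1e-9, exhaustive = TRUE))
  fit_fast <- estimateMCD(X, estimatorConfig(k = 7 / 12 + 1e-9,
                                             n_trials = 500, seed = 21))
  expect_identical(fit_ex$h, h)
  expect_equal(fit_fast$objective, fit_ex$objective, tolerance = 1e-12)
  # independent brute-force enumeration of all C(12,7) = 792 subsets
  expect_equal(fit_ex$objective, oracleMCDObjective(X, 7), tolerance = 1e-12)
})

test_that("exhaustive MVE matches an independent elemental-subset enumeration", {
  X <- clusterFixture()
  h <- 7L
  cfg <- estimatorConfig(k = 7 / 12 + 1e-9, exhaustive = TRUE, rescale = FALSE,
                         reweight = FALSE)
  fit <- estimateMVE(X, cfg)
  expect_equal(fit$objective, oracleMVEObjective(X, 7), tolerance = 1e-12)
  # fast mode with ample trials finds the same optimum
  fit_fast <- estimateMVE(X, estimatorConfig(k = 7 / 12 + 1e-9,
                                             n_trials = 2000, seed = 5))
  expect_equal(fit_fast$objective, fit$objective, tolerance = 1e-12)
})

test_that("robust fits ignore a gross outlier where the sample fit follows it", {
  X <- outlierFixture()  # 20-point cluster + far outlier in row 21
  cfg <- estimatorConfig(seed = 8)
  fit_mcd <- estimateMCD(X, cfg)
  fit_mve <- estimateMVE(X, cfg)
  expect_false(21L %in% fit_mcd$retained)
  expect_false(21L %in% fit_mve$retained)
  # MVE location inside the cluster bounding box; outlier far outside the
  # fitted ellipsoid
  box <- apply(X[1:20, ], 2, range)
  expect_true(all(fit_mve$location >= box[1, ] & fit_mve$location <= box[2, ]))
  expect_gt(mahalanobisD2(fit_mve, X[21, ]),
            max(mahalanobisD2(fit_mve, X[1:20, ])))

  # adding the outlier barely moves the robust locations but drags the
  # sample location
  far <- rbind(X[1:20, ], c(2500, -3000))
  shift <- function(f) sqrt(sum((f(far)$location - f(X[1:20, , drop = FALSE])$location)^2))
  expect_lt(shift(function(Y) estimateMCD(Y, cfg)), 0.5)
  expect_lt(shift(function(Y) estimateMVE(Y, cfg)), 0.5)
  expect_gt(shift(estimateSample), 50)
})

test_that("MVE ellipsoid at h = m covers every point (raw estimate)", {
  set.seed(31)
  X <- matrix(rnorm(60), 30, 2)
  fit <- estimateMVE(X, estimatorConfig(k = 1.0, rescale = FALSE, seed = 2))
  d2 <- mahalanobisD2(fit, X)
  expect_true(all(d2 <= 1 + 1e-8))
  expect_identical(sort(fit$retained), 1:30)
})

test_that("exhaustive estimators and the sample estimator are affine equivariant", {
  X <- clusterFixture()
  A <- matrix(c(2, 0.5, -0.3, 1.5), 2, 2)
  b <- c(1, -2)
  Y <- X %*% t(A) + rep(b, each = nrow(X))
  cfg <- estimatorConfig(k = 0.7, exhaustive = TRUE, rescale = FALSE,
                         reweight = FALSE)
  for (est in list(estimateSample,
                   function(Z) estimateMCD(Z, cfg),
                   function(Z) estimateMVE(Z, cfg))) {
    fx <- est(X); fy <- est(Y)
    expect_equal(fy$location, as.numeric(A %*% fx$location + b),
                 tolerance = 1e-8)
    expect_equal(fy$scatter, A %*% fx$scatter %*% t(A), tolerance = 1e-8)
    # hence identical D^2 for transformed query points
    q <- rbind(c(0, 0), c(3, 1))
    expect_equal(mahalanobisD2(fy, q %*% t(A) + rep(b, each = 2)),
                 mahalanobisD2(fx, q), tolerance = 1e-8)
  }
})

test_that("concentration steps never increase the covariance determinant", {
  np <- nicheParams()
  s <- sampleIdealised(np, 60, seed = 17)
  X <- s$X
  set.seed(7)
  for (rep in 1:20) {
    idx <- sample.int(60, 3)
    fit <- nicheD2:::.concentrate(X, idx, h = 33L, max_csteps = 100L)
    if (is.null(fit)) next
    expect_true(all(diff(fit$path) <= abs(fit$path[-length(fit$path)]) * 1e-12))
  }
})

test_that("MCD enforces its sample-size floor; MVE only needs h >= n + 1", {
  np <- nicheParams()
  s9 <- sampleIdealised(np, 9, seed = 5)
  expect_error(estimateMCD(s9, estimatorConfig(seed = 1)),
               class = "sampleSizeError")
  s10 <- sampleIdealised(np, 10, seed = 5)
  expect_s3_class(estimateMCD(s10, estimatorConfig(seed = 1)),
                  "locationScatter")
  expect_s3_class(estimateMVE(s9, estimatorConfig(seed = 1)),
                  "locationScatter")
})

test_that("exhaustive modes refuse oversized enumerations", {
  np <- nicheParams()
  s <- sampleIdealised(np, 60, seed = 2)
  expect_error(estimateMCD(s, estimatorConfig(exhaustive = TRUE)),
               class = "sizeError")  # choose(60, 31) >> 1e6
})

test_that("estimators read plain CSV and fits survive a JSON round trip", {
  np <- nicheParams()
  s <- sampleIdealised(np, 30, seed = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(s$X), csv, row.names = FALSE)
  fit_csv <- estimateSample(csv)
  fit_mat <- estimateSample(s$X)
  expect_equal(fit_csv$location, fit_mat$location)
  expect_equal(fit_csv$scatter, fit_mat$scatter)

  js <- withr::local_tempfile(fileext = ".json")
  writeLocationScatter(fit_mat, js)
  back <- readLocationScatter(js)
  expect_equal(back$location, fit_mat$location)
  expect_equal(back$scatter, fit_mat$scatter, tolerance = 1e-12)
  expect_identical(back$method, "sample")
})
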