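test_that("one-predictor PLS equals simple least-squares regression", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "v"))
  y <- rep(c(0, 1), 15)
  fit <- fitPLSDA(x, y, nLV = 1)
  expect_equal(unname(predictScores(fit, x)), olsFitted(scale(x), y),
               tolerance = 1e-10)
})

test_that("full-rank PLS reproduces the least-squares oracle", {
  set.seed(2)
  n <- 20; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(0, 1), each = n / 2)
  fit <- fitPLSDA(X, y, nLV = p, scaling = "auto")
  Xs <- applyScaler(X, fit@scaling)
  expect_lt(max(abs(predictScores(fit, X) - olsFitted(Xs, y))), 1e-8)
})

test_that("well-separated clusters are classified without training error", {
  d <- makeTwoClusterData(n = 24, p = 4, d = 6, seed = 3)
  fit <- fitPLSDA(d$X, d$y, nLV = 2)
  pred <- classifyScores(predictScores(fit, d$X), fit@threshold)
  expect_equal(metricNMC(d$y, pred), 0)
})

test_that("weights are orthonormal and scores orthogonal", {
  d <- makeTwoClusterData(n = 30, p = 8, d = 2, nInformative = 3, seed = 4)
  fit <- fitPLSDA(d$X, d$y, nLV = 5)
  WtW <- crossprod(fit@weights)
  expect_equal(WtW, diag(ncol(WtW)), tolerance = 1e-8,
               ignore_attr = TRUE)
  Tn <- fit@scores
  G <- crossprod(Tn) / outer(sqrt(colSums(Tn^2)), sqrt(colSums(Tn^2)))
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("coefficient prediction equals the sequential LV expansion", {
  d <- makeTwoClusterData(n = 26, p = 7, d = 1.5, seed = 5)
  fit <- fitPLSDA(d$X, d$y, nLV = 4)
  viaB <- predictScores(fit, d$X)
  viaT <- drop(fit@scores %*% fit@yLoadings) + fit@yMean
  expect_equal(viaB, viaT, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the fit is deterministic", {
  d <- makeTwoClusterData(n = 30, p = 10, d = 1, seed = 6)
  f1 <- fitPLSDA(d$X, d$y, nLV = 3)
  f2 <- fitPLSDA(d$X, d$y, nLV = 3)
  expect_identical(f1@coefficients, f2@coefficients)
  expect_identical(f1@scores, f2@scores)
})

test_that("rank exhaustion truncates the model with a warning", {
  set.seed(7)
  X <- matrix(rnorm(12), 6, 2)
  X <- cbind(X, X[, 1] + X[, 2])  # rank 2 after centering
  y <- c(0, 1, 0, 1, 0, 1)
  expect_warning(fit <- fitPLSDA(X, y, nLV = 3), "truncated|rank")
  expect_lte(fit@nLV, 2L)
})

test_that("prediction identities hold at the training mean", {
  d <- makeTwoClusterData(n = 20, p = 5, d = 2, seed = 8)
  fit <- fitPLSDA(d$X, d$y, nLV = 2)
  at_mean <- matrix(colMeans(d$X), 1)
  expect_equal(unname(predictScores(fit, at_mean)), fit@yMean,
               tolerance = 1e-12)
  expect_error(predictScores(fit, d$X[, 1:3]), "column count")
})

test_that("classification thresholds with ties going to the control class", {
  expect_identical(classifyScores(c(0.9, 0.1), 0.5), c(1L, 0L))
  expect_identical(classifyScores(0.5, 0.5), 0L)
  expect_identical(classifyScores(c(0.6, 0.7), 0.5), c(1L, 1L))
})

test_that("VIP satisfies its normalization identity on arbitrary fits", {
  for (seed in 1:5) {
    d <- makeTwoClusterData(n = 24, p = 9, d = runif(1, 0.5, 3),
                            nInformative = sample(1:9, 1), seed = seed)
    fit <- fitPLSDA(d$X, d$y, nLV = sample(1:4, 1))
    vip <- computeVIP(fit)
    expect_lt(abs(mean(vip^2) - 1), 1e-10)
  }
})

test_that("VIP is maximal on the informative analyte and symmetric on duplicates", {
  set.seed(9)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("V", 1:6)))
  X[, 4] <- X[, 4] + 5 * y  # single informative column, d = 5
  fit <- fitPLSDA(X, y, nLV = 2)
  vip <- computeVIP(fit)
  expect_equal(names(which.max(vip)), "V4")

  set.seed(10)
  Z <- matrix(rnorm(n), n, 1)
  Xdup <- cbind(a = Z[, 1] + 3 * y, b = Z[, 1] + 3 * y + rnorm(n, sd = 1e-9))
  fitd <- suppressWarnings(fitPLSDA(Xdup, y, nLV = 1))
  vipd <- computeVIP(fitd)
  expect_equal(unname(vipd[1]), unname(vipd[2]), tolerance = 1e-4)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  d <- makeTwoClusterData(n = 30, p = 8, d = 1.5, nInformative = 4, seed = 11)
  fit <- fitPLSDA(d$X, d$y, nLV = 3)
  ref <- mixOmics::pls(scale(d$X), d$y, ncomp = 3, mode = "regression",
                       scale = FALSE)
  pref <- predict(ref, scale(d$X))$predict[, 1, 3]
  expect_equal(unname(predictScores(fit, d$X)), unname(pref),
               tolerance = 1e-8)
})

test_that("a model survives JSON serialization", {
  d <- makeTwoClusterData(n = 20, p = 5, d = 2, seed = 12)
  fit <- fitPLSDA(d$X, d$y, nLV = 2)
  path <- withr::local_tempfile(fileext = ".json")
  writePLSDAModel(fit, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$nLV, 2)
  expect_equal(x$coefficients, unname(fit@coefficients), tolerance = 1e-12)
  expect_equal(matrix(x$weights$values, x$weights$dim[1]),
               unname(fit@weights), tolerance = 1e-12)
})
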