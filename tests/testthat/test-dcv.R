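co27 <- generateCohort(defaultCohortSpec(seed = 11))

test_that("every sample is scored exactly once per repetition", {
  res <- doubleCrossValidate(co27, dcvControl(nRepetitions = 3), seed = 1)
  expect_false(anyNA(res@outerScores))
  expect_false(anyNA(res@outerPredicted))
  expect_equal(dim(res@outerScores), c(27, 3))
  # fold assignments cover all samples and respect stratification
  for (r in 1:3) {
    f <- res@outerFolds[, r]
    expect_setequal(sort(unique(f)), 1:5)
    for (k in 1:5) {
      cls <- res@truth[f == k]
      expect_true(any(cls == 1) && any(cls == 0))
    }
  }
})

test_that("identical seeds reproduce the identical DCV result", {
  r1 <- doubleCrossValidate(co27, dcvControl(nRepetitions = 3), seed = 5)
  r2 <- doubleCrossValidate(co27, dcvControl(nRepetitions = 3), seed = 5)
  expect_identical(r1@outerScores, r2@outerScores)
  expect_identical(r1@chosenLV, r2@chosenLV)
  expect_identical(r1@submodelCoefficients, r2@submodelCoefficients)
  r3 <- doubleCrossValidate(co27, dcvControl(nRepetitions = 3), seed = 6)
  expect_false(identical(r1@outerScores, r3@outerScores))
})

test_that("rates live on the percent scale and summaries carry SEM", {
  res <- doubleCrossValidate(co27, dcvControl(nRepetitions = 4), seed = 2)
  rates <- c(res@outerAccuracy, res@innerAccuracy, res@sfRate, res@cntRate)
  expect_true(all(rates >= 0 & rates <= 100))
  s <- dcvSummary(res)
  expect_equal(s$sem[1], sd(res@outerAccuracy) / sqrt(4))
  expect_equal(s$mean[2], mean(res@innerAccuracy))
})

test_that("stored outer submodels reproduce the held-out scores (no leakage)", {
  res <- doubleCrossValidate(co27, dcvControl(nRepetitions = 2), seed = 3)
  X <- concentrations(co27)
  y <- classCode(co27)
  for (r in 1:2) {
    folds <- res@outerFolds[, r]
    for (f in sort(unique(folds))) {
      tr <- which(folds != f); te <- which(folds == f)
      # refit from scratch using only the training rows of this fold
      fit <- suppressWarnings(
        fitPLSDA(X[tr, , drop = FALSE], y[tr], nLV = res@chosenLV[f, r]))
      expect_equal(unname(predictScores(fit, X[te, , drop = FALSE])),
                   unname(res@outerScores[te, r]), tolerance = 1e-10)
      expect_equal(unname(fit@coefficients),
                   unname(res@submodelCoefficients[, (r - 1) * 5 + f]),
                   tolerance = 1e-10)
    }
  }
})

test_that("permuted labels drive the outer accuracy to chance", {
  set.seed(99)
  yPerm <- sample(as.character(classLabels(co27)))
  scrambled <- CohortTable(concentrations(co27), yPerm)
  res <- doubleCrossValidate(scrambled, dcvControl(nRepetitions = 20),
                             seed = 4)
  expect_gt(mean(outerAccuracy(res)), 35)
  expect_lt(mean(outerAccuracy(res)), 65)
})

test_that("strong separation keeps the selected model small", {
  res <- doubleCrossValidate(co27, dcvControl(nRepetitions = 10), seed = 7)
  expect_gte(mean(chosenLV(res) <= 3), 0.9)
  expect_lte(modalLV(res), 3L)
})

test_that("infeasible stratification names the limiting class", {
  tiny <- CohortTable(matrix(runif(12, 1, 2), 4, 3,
                             dimnames = list(paste0("s", 1:4),
                                             c("a", "b", "c"))),
                      c("SF", "CNT", "CNT", "CNT"))
  expect_error(suppressWarnings(doubleCrossValidate(tiny, dcvControl())),
               "class SF")
})

test_that("fold counts shrink with a warning when a class is small", {
  small <- generateCohort(defaultCohortSpec(nSF = 4, nCNT = 8, seed = 8))
  expect_warning(
    res <- doubleCrossValidate(small, dcvControl(nOuterFolds = 6,
                                                 nRepetitions = 2), seed = 1),
    "reduced")
  expect_false(anyNA(res@outerScores))
})

test_that("the final model refits all samples at the modal complexity", {
  res <- doubleCrossValidate(co27, dcvControl(nRepetitions = 3), seed = 9)
  fit <- finalPLSDAModel(co27, res)
  expect_s4_class(fit, "PLSDAModel")
  expect_equal(fit@nLV, modalLV(res))
  expect_equal(nrow(fit@scores), 27)
})
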