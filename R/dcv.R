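#' @include metrics.R
NULL

#' Control parameters for double cross-validation
#'
#' Defaults (5 outer folds, 5 inner folds, 20 repetitions, up to 10 LVs) are
#' sized for a study-scale cohort of ~27 samples: each outer fold holds 5-6
#' samples, and the spread over repetitions yields the mean +/- SEM
#' reporting convention.
#'
#' @param nOuterFolds,nInnerFolds Stratified fold counts (>= 2). Folds are
#'   reduced with a warning if a class is too small.
#' @param nRepetitions Number of repeated DCV cycles.
#' @param maxLV Largest number of latent variables the inner loop may select.
#' @param scaling Column scaling, see [fitScaler()]; fitted inside every
#'   training partition.
#' @param threshold Classification cutoff on the continuous score.
#' @return A named list of class `"dcvControl"`.
#' @export
dcvControl <- function(nOuterFolds = 5L, nInnerFolds = 5L,
                       nRepetitions = 20L, maxLV = 10L,
                       scaling = "auto", threshold = 0.5) {
  stopifnot(nOuterFolds >= 2L, nInnerFolds >= 2L, nRepetitions >= 1L,
            maxLV >= 1L)
  structure(list(nOuterFolds = as.integer(nOuterFolds),
                 nInnerFolds = as.integer(nInnerFolds),
                 nRepetitions = as.integer(nRepetitions),
                 maxLV = as.integer(maxLV), scaling = scaling,
                 threshold = threshold),
            class = "dcvControl")
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so every fold gets at least one member of each class whenever
# the class size allows it. Consumes the current RNG stream.
.stratifiedFolds <- function(y01, k) {
  minClass <- min(table(y01))
  if (minClass < 2L) {
    lim <- if (sum(y01 == 1) < sum(y01 == 0)) "SF" else "CNT"
    stop("stratification infeasible: class ", lim, " has fewer than 2 samples")
  }
  if (k > minClass) {
    warning("folds reduced from ", k, " to ", minClass,
            " (limited by the smaller class)")
    k <- minClass
  }
  folds <- integer(length(y01))
  for (cl in unique(y01)) {
    idx <- sample(which(y01 == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Scale + NIPALS on a training partition, warning-free (used in hot loops).
.plsFit <- function(X, y01, maxLV, scaling) {
  sc <- fitScaler(X, method = scaling)
  ym <- mean(y01)
  a <- min(maxLV, nrow(X) - 1L, ncol(X))
  fit <- .nipalsPLS1(applyScaler(X, sc), y01 - ym, a)
  list(sc = sc, ym = ym, fit = fit)
}

# Score matrix (samples x 1..A LVs) for new raw rows.
.plsPredictPath <- function(obj, Xnew) {
  applyScaler(Xnew, obj$sc) %*% obj$fit$coefPath + obj$ym
}

#' Class "DCVResult": repeated double cross-validation output
#'
#' Per-repetition held-out predictions, the latent-variable counts chosen by
#' the inner loop, inner/outer classification rates (percent), and the
#' regression coefficient vectors of all outer submodels (used by the rank
#' product selector).
#'
#' @slot truth 0/1 labels (SF = 1), one per sample.
#' @slot outerScores,outerPredicted Sample x repetition matrices of held-out
#'   continuous scores and hard labels; every sample is predicted exactly
#'   once per repetition.
#' @slot chosenLV Outer-fold x repetition matrix of selected LV counts.
#' @slot innerAccuracy,outerAccuracy,sfRate,cntRate Per-repetition rates (%).
#' @slot submodelCoefficients Analyte x (outer fold * repetition) matrix of
#'   outer-model regression coefficients (scaled-X scale).
#' @slot outerFolds Sample x repetition matrix of outer fold assignments
#'   (enough to reconstruct any outer submodel).
#' @slot control The [dcvControl()] list used.
#' @slot seed Root seed of the run.
#' @slot analyteNames,sampleIds Dimension names.
#' @name DCVResult-class
#' @exportClass DCVResult
setClass("DCVResult",
  representation(truth = "numeric", outerScores = "matrix",
                 outerPredicted = "matrix", chosenLV = "matrix",
                 innerAccuracy = "numeric", outerAccuracy = "numeric",
                 sfRate = "numeric", cntRate = "numeric",
                 submodelCoefficients = "matrix", outerFolds = "matrix",
                 control = "list",
                 seed = "integer", analyteNames = "character",
                 sampleIds = "character"))

#' Repeated stratified double cross-validation of PLS-DA
#'
#' For each repetition: a stratified outer split; for each outer training
#' set, a stratified inner cross-validation over 1..`maxLV` latent variables
#' selects the LV count minimizing the inner number of misclassifications
#' (ties go to fewer LVs — parsimony); the model is refit on the outer
#' training set at the chosen complexity and scores the held-out fold.
#' Scaling is fitted inside every training partition, so no information
#' leaks from held-out samples into either loop. Inner accuracy (the
#' model-selection rate) is the inner-CV accuracy at the selected LV,
#' averaged over outer folds; outer accuracy pools each repetition's
#' held-out predictions. Summaries are mean +/- SEM over repetitions.
#'
#' @param table A [CohortTable-class] with both classes present.
#' @param control A [dcvControl()] list.
#' @param seed Integer seed; fixed seed implies an identical result.
#' @return A [DCVResult-class].
#' @examples
#' cohort <- generateCohort(defaultCohortSpec(seed = 11))
#' res <- doubleCrossValidate(cohort, dcvControl(nRepetitions = 5), seed = 1)
#' dcvSummary(res)
#' @export
doubleCrossValidate <- function(table, control = dcvControl(), seed = 1L) {
  stopifnot(is(table, "CohortTable"), inherits(control, "dcvControl"))
  X <- concentrations(table)
  y <- classCode(table)
  .checkBothClasses(y)
  n <- nrow(X); p <- ncol(X)
  minClass <- min(sum(y == 1), sum(y == 0))
  if (control$nOuterFolds > minClass)
    warning("outer folds reduced from ", control$nOuterFolds, " to ",
            minClass, " (limited by the smaller class)")
  R <- control$nRepetitions
  outerScores <- matrix(NA_real_, n, R)
  outerPred <- matrix(NA_integer_, n, R)
  chosen <- NULL
  innerAcc <- outerAcc <- sfRate <- cntRate <- numeric(R)
  coefs <- NULL
  foldAssign <- matrix(NA_integer_, n, R)
  for (r in seq_len(R)) {
    repRes <- withSeed(deriveSeed(seed, sprintf("dcv-rep-%d", r)), {
      folds <- suppressWarnings(.stratifiedFolds(y, control$nOuterFolds))
      kOut <- max(folds)
      repChosen <- integer(kOut)
      repInner <- numeric(kOut)
      repCoefs <- matrix(NA_real_, p, kOut)
      scores <- numeric(n)
      for (f in seq_len(kOut)) {
        trainIdx <- which(folds != f)
        testIdx <- which(folds == f)
        Xtr <- X[trainIdx, , drop = FALSE]
        ytr <- y[trainIdx]
        # inner loop: CV misclassification per candidate LV count
        innerFolds <- suppressWarnings(
          .stratifiedFolds(ytr, control$nInnerFolds))
        kIn <- max(innerFolds)
        nmcPerLV <- numeric(control$maxLV)
        for (g in seq_len(kIn)) {
          inTr <- which(innerFolds != g)
          inTe <- which(innerFolds == g)
          obj <- .plsFit(Xtr[inTr, , drop = FALSE], ytr[inTr],
                         control$maxLV, control$scaling)
          sc <- .plsPredictPath(obj, Xtr[inTe, , drop = FALSE])
          a <- ncol(sc)
          # LVs beyond this fold's rank reuse its deepest model
          for (lv in seq_len(control$maxLV)) {
            pred <- as.integer(sc[, min(lv, a)] > control$threshold)
            nmcPerLV[lv] <- nmcPerLV[lv] + sum(pred != ytr[inTe])
          }
        }
        bestLV <- which.min(nmcPerLV)  # first minimum = fewest LVs
        repChosen[f] <- bestLV
        repInner[f] <- 100 * (1 - nmcPerLV[bestLV] / length(trainIdx))
        # refit on the full outer training set at the selected complexity
        obj <- .plsFit(Xtr, ytr, bestLV, control$scaling)
        scPath <- .plsPredictPath(obj, X[testIdx, , drop = FALSE])
        scores[testIdx] <- scPath[, ncol(scPath)]
        repCoefs[, f] <- obj$fit$coefPath[, ncol(scPath)]
      }
      list(scores = scores, chosen = repChosen, inner = repInner,
           coefs = repCoefs, folds = folds)
    })
    outerScores[, r] <- repRes$scores
    outerPred[, r] <- as.integer(repRes$scores > control$threshold)
    chosen <- cbind(chosen, repRes$chosen)
    innerAcc[r] <- mean(repRes$inner)
    pred <- outerPred[, r]
    outerAcc[r] <- 100 * mean(pred == y)
    sfRate[r] <- 100 * mean(pred[y == 1] == 1)
    cntRate[r] <- 100 * mean(pred[y == 0] == 0)
    coefs <- cbind(coefs, repRes$coefs)
    foldAssign[, r] <- repRes$folds
  }
  rownames(outerScores) <- rownames(outerPred) <- rownames(X)
  rownames(coefs) <- colnames(X)
  new("DCVResult", truth = y, outerScores = outerScores,
      outerPredicted = outerPred, chosenLV = chosen,
      innerAccuracy = innerAcc, outerAccuracy = outerAcc,
      sfRate = sfRate, cntRate = cntRate, submodelCoefficients = coefs,
      outerFolds = foldAssign, control = unclass(control),
      seed = as.integer(seed),
      analyteNames = colnames(X), sampleIds = rownames(X))
}

#' @describeIn DCVResult-class Per-repetition outer classification rate (%).
#' @export
setMethod("outerAccuracy", "DCVResult", function(x, ...) x@outerAccuracy)

#' @describeIn DCVResult-class Per-repetition inner (model-selection)
#'   classification rate (%).
#' @export
setMethod("innerAccuracy", "DCVResult", function(x, ...) x@innerAccuracy)

#' @describeIn DCVResult-class Outer-fold x repetition matrix of selected LV
#'   counts.
#' @export
setMethod("chosenLV", "DCVResult", function(x, ...) x@chosenLV)

#' @describeIn DCVResult-class Summary data.frame: mean and SEM (over
#'   repetitions) of the outer, inner and per-class rates, plus the modal
#'   selected LV count.
#' @export
setMethod("dcvSummary", "DCVResult", function(x, ...) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  data.frame(
    statistic = c("outer_accuracy", "inner_accuracy", "sf_rate", "cnt_rate"),
    mean = c(mean(x@outerAccuracy), mean(x@innerAccuracy),
             mean(x@sfRate), mean(x@cntRate)),
    sem = c(sem(x@outerAccuracy), sem(x@innerAccuracy),
            sem(x@sfRate), sem(x@cntRate)),
    units = "%", stringsAsFactors = FALSE)
})

setMethod("show", "DCVResult", function(object) {
  s <- dcvSummary(object)
  cat("DCVResult:", length(object@truth), "samples |",
      ncol(object@outerScores), "repetitions\n")
  cat(sprintf("  outer accuracy: %.1f +/- %.1f %%\n",
              s$mean[1], s$sem[1]))
  cat(sprintf("  inner accuracy: %.1f +/- %.1f %%\n",
              s$mean[2], s$sem[2]))
  cat("  modal chosen LV:", modalLV(object), "\n")
})

#' Modal selected latent-variable count
#'
#' The most frequent LV count across all outer fits (ties go to the smaller
#' count) — the complexity used for the final interpretable model.
#'
#' @param x A [DCVResult-class].
#' @return Integer LV count.
#' @export
modalLV <- function(x) {
  stopifnot(is(x, "DCVResult"))
  vals <- sort(unique(as.vector(x@chosenLV)))
  counts <- vapply(vals, function(v) sum(x@chosenLV == v), numeric(1))
  as.integer(vals[which.max(counts)])  # first maximum = smallest LV
}

#' Final interpretable PLS-DA model
#'
#' Refits on all samples at the modal LV count selected across the DCV outer
#' fits — the model whose scores and VIP are reported (score-plot analogue).
#'
#' @param table The [CohortTable-class] used for the DCV run.
#' @param dcv The corresponding [DCVResult-class].
#' @return A [PLSDAModel-class].
#' @export
finalPLSDAModel <- function(table, dcv) {
  stopifnot(is(table, "CohortTable"), is(dcv, "DCVResult"))
  fitPLSDA(concentrations(table), classLabels(table), nLV = modalLV(dcv),
           scaling = dcv@control$scaling, threshold = dcv@control$threshold)
}
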