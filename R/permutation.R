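#' @include selection.R
NULL

#' Class "PermutationResult": permutation null of NMC, AUROC and DQ2
#'
#' Null distributions built by re-running the entire double cross-validation
#' (scaling, LV selection, outer prediction) on label-shuffled data, plus the
#' observed statistics and their add-one empirical p-values.
#'
#' @slot nPermutations Number of permutations.
#' @slot nullNMC,nullAUROC,nullDQ2 Per-permutation statistic vectors.
#' @slot observedNMC,observedAUROC,observedDQ2 Statistics on the unpermuted
#'   labels, computed identically (one DCV pass, pooled outer predictions).
#' @slot pNMC,pAUROC,pDQ2 Empirical p-values (NMC: smaller is extreme;
#'   AUROC, DQ2: greater is extreme).
#' @name PermutationResult-class
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(nPermutations = "integer", nullNMC = "numeric",
                 nullAUROC = "numeric", nullDQ2 = "numeric",
                 observedNMC = "numeric", observedAUROC = "numeric",
                 observedDQ2 = "numeric", pNMC = "numeric",
                 pAUROC = "numeric", pDQ2 = "numeric"))

# One single-pass DCV evaluation: pooled held-out scores -> three statistics.
.dcvStatistics <- function(table, y, control, seed) {
  tmp <- CohortTable(concentrations(table),
                     ifelse(y == 1, "SF", "CNT"),
                     sampleIds = rownames(concentrations(table)))
  res <- doubleCrossValidate(tmp, control, seed = seed)
  scores <- res@outerScores[, 1]
  pred <- res@outerPredicted[, 1]
  c(nmc = metricNMC(y, pred),
    auroc = metricAUROC(y, scores),
    dq2 = metricDQ2(y, scores))
}

#' Permutation test of the validated classification
#'
#' For each permutation, the class labels are shuffled uniformly and the
#' complete double cross-validation is re-run from scratch — scaling fits,
#' latent-variable selection and outer prediction all happen inside the
#' permuted world, so the null statistics inherit every source of
#' optimistic bias the observed statistic could have. NMC, AUROC and DQ2
#' are computed on the pooled outer predictions of a single DCV pass per
#' permutation; the observed statistics use the identical computation on
#' the unpermuted labels, preserving exchangeability. Rows of X are never
#' touched, so the analyte correlation structure is preserved under the
#' null.
#'
#' @param table A [CohortTable-class].
#' @param control A [dcvControl()]; its `nRepetitions` is forced to 1 for
#'   the per-permutation passes.
#' @param nPermutations Number of label permutations (>= 1; the study-scale
#'   default is 1000).
#' @param seed Integer seed driving both the shuffles and the fold draws.
#' @return A [PermutationResult-class].
#' @examples
#' cohort <- generateCohort(defaultCohortSpec(seed = 11))
#' permutationNull(cohort, nPermutations = 20, seed = 1)
#' @export
permutationNull <- function(table, control = dcvControl(),
                            nPermutations = 1000L, seed = 1L) {
  stopifnot(is(table, "CohortTable"), nPermutations >= 1L)
  control$nRepetitions <- 1L
  class(control) <- "dcvControl"
  y <- classCode(table)
  .checkBothClasses(y)
  obs <- .dcvStatistics(table, y, control, seed = deriveSeed(seed, "observed"))
  B <- as.integer(nPermutations)
  nullStats <- matrix(NA_real_, B, 3)
  for (b in seq_len(B)) {
    yPerm <- withSeed(deriveSeed(seed, sprintf("perm-%d", b)), sample(y))
    nullStats[b, ] <- .dcvStatistics(table, yPerm, control,
                                     seed = deriveSeed(seed,
                                                       sprintf("perm-dcv-%d", b)))
  }
  new("PermutationResult", nPermutations = B,
      nullNMC = nullStats[, 1], nullAUROC = nullStats[, 2],
      nullDQ2 = nullStats[, 3],
      observedNMC = obs[["nmc"]], observedAUROC = obs[["auroc"]],
      observedDQ2 = obs[["dq2"]],
      pNMC = empiricalPValue(nullStats[, 1], obs[["nmc"]], "smaller"),
      pAUROC = empiricalPValue(nullStats[, 2], obs[["auroc"]], "greater"),
      pDQ2 = empiricalPValue(nullStats[, 3], obs[["dq2"]], "greater"))
}

#' @describeIn PermutationResult-class Null distributions as a data.frame
#'   (one row per permutation; columns `nmc`, `auroc`, `dq2`).
#' @export
setMethod("nullDistributions", "PermutationResult", function(x, ...) {
  data.frame(nmc = x@nullNMC, auroc = x@nullAUROC, dq2 = x@nullDQ2)
})

#' @describeIn PermutationResult-class Named vector of observed statistics.
#' @export
setMethod("observedStatistics", "PermutationResult", function(x, ...) {
  c(nmc = x@observedNMC, auroc = x@observedAUROC, dq2 = x@observedDQ2)
})

#' @describeIn PermutationResult-class Named vector of empirical p-values.
#' @export
setMethod("pValues", "PermutationResult", function(x, ...) {
  c(nmc = x@pNMC, auroc = x@pAUROC, dq2 = x@pDQ2)
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult:", object@nPermutations, "permutations\n")
  cat(sprintf("  NMC   observed %g, p = %.4g\n",
              object@observedNMC, object@pNMC))
  cat(sprintf("  AUROC observed %.3f, p = %.4g\n",
              object@observedAUROC, object@pAUROC))
  cat(sprintf("  DQ2   observed %.3f, p = %.4g\n",
              object@observedDQ2, object@pDQ2))
})
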