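#' @include plsda.R
NULL

.code01 <- function(y) {
  if (is.factor(y) || is.character(y)) as.numeric(as.character(y) == "SF")
  else as.numeric(y)
}

#' Number of misclassifications (NMC)
#'
#' @param truth True 0/1 labels (or a `CNT`/`SF` factor).
#' @param predicted Predicted 0/1 labels of the same length.
#' @return Integer count of disagreements.
#' @export
metricNMC <- function(truth, predicted) {
  truth <- .code01(truth); predicted <- .code01(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  sum(truth != predicted)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen case (SF) score exceeds a randomly
#' chosen control (CNT) score, with ties counted 1/2. Computed from midranks,
#' which is exactly the normalized Mann-Whitney U statistic.
#'
#' @param truth True 0/1 labels; both classes must be present.
#' @param scores Continuous discriminant scores.
#' @return AUROC in \[0, 1\].
#' @export
metricAUROC <- function(truth, scores) {
  truth <- .code01(truth)
  stopifnot(length(truth) == length(scores))
  nPos <- sum(truth == 1); nNeg <- sum(truth == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Discriminant Q2 (DQ2)
#'
#' Cross-validated explained variance of the 0/1 class response in which
#' residuals of predictions that overshoot their own class label are zeroed
#' (`y = 1` with `yhat > 1`, or `y = 0` with `yhat < 0` count as perfect):
#' `DQ2 = 1 - sum(e^2) / sum((y - mean(y))^2)`. DQ2 is never below the plain
#' Q2 on the same predictions, because truncation can only shrink squared
#' residuals.
#'
#' @param truth True 0/1 labels.
#' @param scores Continuous predicted responses.
#' @return DQ2 value (<= 1; can be negative for models worse than the mean).
#' @export
metricDQ2 <- function(truth, scores) {
  y <- .code01(truth)
  stopifnot(length(y) == length(scores))
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("zero total sum of squares: single-class labels")
  e <- y - scores
  e[y == 1 & scores > 1] <- 0
  e[y == 0 & scores < 0] <- 0
  1 - sum(e^2) / tss
}

#' Empirical permutation p-value (add-one estimator)
#'
#' `p = (#{null at least as extreme as observed} + 1) / (n + 1)`, which is
#' never zero and achieves its floor `1/(n+1)` when the observed statistic
#' beats the whole null. NMC is extreme when small; AUROC and DQ2 when large.
#'
#' @param null Numeric vector of null statistics (non-empty).
#' @param observed Observed statistic.
#' @param direction `"greater"` (large values extreme) or `"smaller"`.
#' @return p-value in `(0, 1]`.
#' @export
empiricalPValue <- function(null, observed,
                            direction = c("greater", "smaller")) {
  direction <- match.arg(direction)
  stopifnot(length(null) >= 1L, is.finite(observed))
  extreme <- if (direction == "greater") sum(null >= observed)
             else sum(null <= observed)
  (extreme + 1) / (length(null) + 1)
}
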