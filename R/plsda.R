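#' @include scaling.R
NULL

#' Class "PLSDAModel": a fitted PLS1 discriminant model
#'
#' PLS regression of the 0/1-coded class response (SF = 1) on the scaled
#' concentration matrix, fitted by NIPALS, plus the discriminant decision
#' rule. Model complexity is the number of latent variables (LVs).
#'
#' @slot weights Analyte x LV weight matrix W (orthonormal columns).
#' @slot xLoadings Analyte x LV loading matrix P.
#' @slot yLoadings Length-LV response loading vector q.
#' @slot scores Training sample x LV score matrix T (orthogonal columns).
#' @slot coefficients Per-analyte regression vector B at the full LV count,
#'   on the scaled-X scale: `yhat = yMean + Xscaled %*% B`.
#' @slot coefPath Analyte x LV matrix of coefficient vectors for models
#'   truncated at 1..LV components (used for fast LV selection).
#' @slot nLV Number of latent variables actually extracted (may be less than
#'   requested if the rank is exhausted).
#' @slot scaling The [ScalingParams-class] fitted on the training rows.
#' @slot yMean Training mean of the 0/1 response.
#' @slot threshold Decision cutoff: predict SF iff score > threshold
#'   (strictly; a score equal to the threshold is assigned to CNT).
#' @slot analyteNames Panel names, in training column order.
#' @name PLSDAModel-class
#' @exportClass PLSDAModel
setClass("PLSDAModel",
  representation(weights = "matrix", xLoadings = "matrix",
                 yLoadings = "numeric", scores = "matrix",
                 coefficients = "numeric", coefPath = "matrix",
                 nLV = "integer", scaling = "ScalingParams",
                 yMean = "numeric", threshold = "numeric",
                 analyteNames = "character"))

setMethod("show", "PLSDAModel", function(object) {
  cat("PLSDAModel:", object@nLV, "LV |", length(object@coefficients),
      "analytes |", nrow(object@scores), "training samples | scaling:",
      object@scaling@method, "\n")
})

# NIPALS PLS1 on an already-scaled X and centered y. Deterministic: the
# single-response weight update w = X'y has a closed form, no iteration or
# random start. Stops early if X or y is deflated to numerical zero.
.nipalsPLS1 <- function(Xs, yc, nLV) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, nLV); P <- matrix(0, p, nLV)
  Tm <- matrix(0, n, nLV); q <- numeric(nLV)
  Xd <- Xs
  a <- 0L
  for (k in seq_len(nLV)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, t) / tt
    qa <- sum(yc * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yc <- yc - qa * t
    W[, k] <- w; P[, k] <- pv; Tm[, k] <- t; q[k] <- qa
    a <- k
  }
  if (a == 0L) stop("degenerate fit: X carries no covariance with y")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  # R = W (P'W)^{-1} maps scaled X to scores; coefficient path is cumulative.
  R <- W %*% solve(t(P) %*% W)
  coefPath <- vapply(seq_len(a), function(k) {
    drop(R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)])
  }, numeric(p))
  coefPath <- matrix(coefPath, nrow = p)
  list(W = W, P = P, Tm = Tm, q = q, coefPath = coefPath, nLV = a)
}

#' Fit a PLS-DA model
#'
#' Scales `X` (training-only parameters), codes the response 0/1 (SF = 1),
#' and runs NIPALS PLS1 with `nLV` latent variables. The fit is fully
#' deterministic. If the data rank is exhausted before `nLV` components the
#' model is truncated with a warning.
#'
#' @param X Raw samples x analytes concentration matrix.
#' @param y Class labels: a factor with levels `CNT`/`SF` or a 0/1 vector.
#' @param nLV Requested number of latent variables (>= 1, at most
#'   `min(nrow(X) - 1, ncol(X))`).
#' @param scaling Column scaling method, see [fitScaler()].
#' @param threshold Decision cutoff on the continuous score (default 0.5).
#' @return A [PLSDAModel-class].
#' @examples
#' spec <- defaultCohortSpec(seed = 3)
#' cohort <- generateCohort(spec)
#' fit <- fitPLSDA(concentrations(cohort), classLabels(cohort), nLV = 2)
#' fit
#' @export
fitPLSDA <- function(X, y, nLV, scaling = "auto", threshold = 0.5) {
  X <- as.matrix(X)
  y <- if (is.factor(y) || is.character(y)) as.numeric(as.character(y) == "SF")
       else as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  .checkBothClasses(y)
  nLV <- as.integer(nLV)
  maxA <- min(nrow(X) - 1L, ncol(X))
  if (nLV < 1L) stop("nLV must be >= 1")
  if (nLV > maxA) {
    warning("nLV reduced to ", maxA, " (rank bound)")
    nLV <- maxA
  }
  sc <- fitScaler(X, method = scaling)
  Xs <- applyScaler(X, sc)
  ym <- mean(y)
  fit <- .nipalsPLS1(Xs, y - ym, nLV)
  if (fit$nLV < nLV)
    warning("rank exhausted: fit truncated at ", fit$nLV, " LV")
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(X)))
  new("PLSDAModel", weights = fit$W, xLoadings = fit$P, yLoadings = fit$q,
      scores = fit$Tm, coefficients = fit$coefPath[, fit$nLV],
      coefPath = fit$coefPath, nLV = fit$nLV, scaling = sc,
      yMean = ym, threshold = threshold, analyteNames = nm)
}

#' Continuous discriminant scores for new samples
#'
#' Applies the stored training scaler, then the linear predictor
#' `yMean + Xscaled %*% B`. Values near 1 indicate SF, near 0 CNT; the
#' output is unbounded.
#'
#' @param model A [PLSDAModel-class].
#' @param X Raw matrix with the training panel's column count.
#' @param nLV Optional truncation to fewer LVs than fitted (uses the stored
#'   coefficient path).
#' @return Numeric score per sample.
#' @export
predictScores <- function(model, X, nLV = NULL) {
  stopifnot(is(model, "PLSDAModel"))
  X <- as.matrix(X)
  if (ncol(X) != length(model@coefficients))
    stop("column count does not match the training panel")
  b <- if (is.null(nLV)) model@coefficients else {
    nLV <- as.integer(nLV)
    stopifnot(nLV >= 1L, nLV <= model@nLV)
    model@coefPath[, nLV]
  }
  drop(applyScaler(X, model@scaling) %*% b) + model@yMean
}

#' Hard class labels from continuous scores
#'
#' Assigns SF (1) iff the score strictly exceeds the threshold; a score
#' exactly at the threshold goes to CNT (0).
#'
#' @param scores Numeric discriminant scores.
#' @param threshold Cutoff, default 0.5 (midpoint of the 0/1 coding).
#' @return Integer 0/1 labels.
#' @export
classifyScores <- function(scores, threshold = 0.5) {
  as.integer(scores > threshold)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with
#' `SSY_a = q_a^2 t_a't_a` (response variance captured by LV `a`) and unit
#' weight columns. Mean squared VIP is exactly 1, so analytes with VIP > 1
#' contribute more than average.
#'
#' @param model A fitted [PLSDAModel-class].
#' @return Named numeric vector of VIP values, one per analyte.
#' @export
computeVIP <- function(model) {
  stopifnot(is(model, "PLSDAModel"))
  ssy <- model@yLoadings^2 * colSums(model@scores^2)
  if (sum(ssy) <= 0) stop("degenerate model: no captured response variance")
  p <- nrow(model@weights)
  vip <- sqrt(p * drop(model@weights^2 %*% ssy) / sum(ssy))
  names(vip) <- model@analyteNames
  vip
}

#' @describeIn PLSDAModel-class VIP values of the fitted model.
#' @export
setMethod("vipScores", "PLSDAModel", function(x, ...) computeVIP(x))

#' Serialize a PLS-DA model to JSON
#'
#' Flattens all matrices (shapes recorded) so a fit can be audited or
#' re-loaded without R serialization.
#'
#' @param model A [PLSDAModel-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writePLSDAModel <- function(model, path) {
  stopifnot(is(model, "PLSDAModel"))
  mat <- function(m) list(dim = dim(m), values = as.numeric(m))
  jsonlite::write_json(list(
    nLV = model@nLV, yMean = model@yMean, threshold = model@threshold,
    analytes = model@analyteNames,
    weights = mat(model@weights), xLoadings = mat(model@xLoadings),
    yLoadings = model@yLoadings, scores = mat(model@scores),
    coefficients = model@coefficients,
    scaling = list(method = model@scaling@method,
                   center = model@scaling@center,
                   scale = model@scaling@scale)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
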