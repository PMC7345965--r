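#' @include generate.R
NULL

#' Class "ScalingParams": column scaling fitted on training data
#'
#' Captures the per-analyte location and scale learned from a training
#' partition. In every cross-validation fold, scaling is fitted on that
#' fold's training rows only and then applied to the held-out rows — the
#' leakage boundary of the whole pipeline.
#'
#' @slot center Per-analyte training means.
#' @slot scale Per-analyte divisors (SD for `"auto"`, sqrt(SD) for
#'   `"pareto"`, 1 for `"center"`/`"none"`).
#' @slot method One of `"auto"`, `"pareto"`, `"center"`, `"none"`.
#' @slot zeroVariance Logical flag per analyte; zero-variance columns are
#'   scaled to exactly 0 so they cannot influence the model.
#' @name ScalingParams-class
#' @exportClass ScalingParams
setClass("ScalingParams",
  representation(center = "numeric", scale = "numeric", method = "character",
                 zeroVariance = "logical"))

#' Fit column scaling on a training matrix
#'
#' @param X Numeric samples x analytes matrix with >= 2 rows.
#' @param method `"auto"` (mean-center, unit variance — the default, because
#'   urinary amino acid levels span two orders of magnitude), `"pareto"`,
#'   `"center"` or `"none"`.
#' @return A [ScalingParams-class]. SDs use the n-1 denominator.
#' @export
fitScaler <- function(X, method = c("auto", "pareto", "center", "none")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  # flag only where the SD is used as divisor; centering alone already
  # sends a constant column to zero
  zero <- if (method %in% c("auto", "pareto")) sd == 0
          else rep(FALSE, ncol(X))
  scl <- switch(method,
    auto = sd,
    pareto = sqrt(sd),
    center = rep(1, ncol(X)),
    none = rep(1, ncol(X)))
  if (method == "none") mu <- rep(0, ncol(X))
  names(scl) <- names(mu) <- colnames(X)
  new("ScalingParams", center = unname(mu), scale = unname(scl),
      method = method, zeroVariance = unname(zero))
}

#' Apply fitted scaling to a (possibly held-out) matrix
#'
#' Computes `(x - center) / scale` per column; columns flagged as
#' zero-variance at fit time map to all zeros.
#'
#' @param X Numeric matrix whose column count matches the fitted params.
#' @param params A [ScalingParams-class] from [fitScaler()].
#' @return The scaled matrix.
#' @export
applyScaler <- function(X, params) {
  stopifnot(is(params, "ScalingParams"))
  X <- as.matrix(X)
  if (ncol(X) != length(params@center))
    stop("column count (", ncol(X), ") does not match scaler (",
         length(params@center), ")")
  out <- sweep(X, 2, params@center, "-")
  div <- params@scale
  div[params@zeroVariance | div == 0] <- 1
  out <- sweep(out, 2, div, "/")
  out[, params@zeroVariance] <- 0
  out
}
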