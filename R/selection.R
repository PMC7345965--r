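#' @include dcv.R
NULL

#' Class "SelectionResult": VIP and rank-product biomarker selection
#'
#' Per-analyte importance from two complementary selectors — VIP from the
#' final all-data model (model-based) and rank product across the DCV outer
#' submodels (resampling-based) — with dense ranks and their top-k consensus.
#'
#' @slot analytes Panel names.
#' @slot vip VIP values from the final model.
#' @slot rp Rank products (geometric mean of per-submodel importance ranks;
#'   >= 1, smaller = consistently more important).
#' @slot vipRank,rpRank Ranks 1..p (1 = most important; ties broken
#'   alphabetically by analyte name).
#' @slot consensus Analytes in the top-k of both rankings.
#' @slot k The consensus cutoff used.
#' @name SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(analytes = "character", vip = "numeric", rp = "numeric",
                 vipRank = "integer", rpRank = "integer",
                 consensus = "character", k = "integer"))

#' Rank product of submodel importances
#'
#' Within each submodel, analytes are ranked by decreasing absolute
#' importance (rank 1 = largest; ties get average ranks); the rank product
#' of an analyte is the geometric mean of its ranks across submodels. An
#' analyte ranked first everywhere attains the floor RP = 1. The statistic
#' depends on the importances only through their within-submodel ranks, so
#' it is invariant to monotone transformations.
#'
#' @param importances Submodel x analyte numeric matrix (>= 2 submodels).
#' @return Named numeric vector of rank products.
#' @export
rankProduct <- function(importances) {
  importances <- as.matrix(importances)
  if (nrow(importances) < 2L) stop("need at least 2 submodels")
  if (any(apply(importances, 1, function(r) all(r == 0))))
    stop("all-zero submodel importances")
  ranks <- t(apply(abs(importances), 1,
                   function(r) rank(-r, ties.method = "average")))
  rp <- exp(colMeans(log(ranks)))
  names(rp) <- colnames(importances)
  rp
}

# Dense 1..p ranking with deterministic alphabetical tie-break.
.rankWithNameTies <- function(values, names, decreasing) {
  ord <- order(if (decreasing) -values else values, names)
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  r
}

#' Consensus of the two selectors
#'
#' Intersection of the top-k analytes by VIP (descending) and by rank
#' product (ascending), ties broken alphabetically.
#'
#' @param vip Named VIP vector.
#' @param rp Named rank-product vector over the same analytes.
#' @param k Consensus cutoff (<= number of analytes).
#' @return Character vector (sorted) of analytes in both top-k sets.
#' @export
consensusSelection <- function(vip, rp, k) {
  stopifnot(length(vip) == length(rp),
            identical(names(vip), names(rp)))
  if (k > length(vip)) stop("k exceeds the number of analytes")
  vr <- .rankWithNameTies(vip, names(vip), decreasing = TRUE)
  rr <- .rankWithNameTies(rp, names(rp), decreasing = FALSE)
  sort(intersect(names(vip)[vr <= k], names(rp)[rr <= k]))
}

#' Biomarker selection from a DCV run
#'
#' Combines the two selectors: VIP computed on the final all-data model
#' (refit at the modal LV count) and rank product of the absolute regression
#' coefficients of every DCV outer submodel. Their top-k consensus is the
#' reported biomarker set.
#'
#' @param table The [CohortTable-class] analyzed.
#' @param dcv The [DCVResult-class] from [doubleCrossValidate()].
#' @param k Consensus cutoff (default 9).
#' @param importance `"coefficients"` (default) feeds the rank product with
#'   the outer-model `|B|`; `"vip"` uses each outer submodel's VIP instead.
#' @return A [SelectionResult-class].
#' @examples
#' cohort <- generateCohort(defaultCohortSpec(seed = 11))
#' res <- doubleCrossValidate(cohort, dcvControl(nRepetitions = 5), seed = 1)
#' selectBiomarkers(cohort, res, k = 9)
#' @export
selectBiomarkers <- function(table, dcv, k = 9L,
                             importance = c("coefficients", "vip")) {
  importance <- match.arg(importance)
  stopifnot(is(table, "CohortTable"), is(dcv, "DCVResult"))
  k <- as.integer(k)
  final <- finalPLSDAModel(table, dcv)
  vip <- computeVIP(final)
  imp <- if (importance == "coefficients") {
    t(abs(dcv@submodelCoefficients))
  } else {
    submodelVIPs(table, dcv)
  }
  rp <- rankProduct(imp)
  vr <- .rankWithNameTies(vip, names(vip), decreasing = TRUE)
  rr <- .rankWithNameTies(rp, names(rp), decreasing = FALSE)
  new("SelectionResult", analytes = names(vip), vip = unname(vip),
      rp = unname(rp), vipRank = vr, rpRank = rr,
      consensus = consensusSelection(vip, rp, k), k = k)
}

#' VIP of every DCV outer submodel
#'
#' Refits each outer training set at its selected LV count (reconstructed
#' from the stored fold assignments) and evaluates VIP — the alternative,
#' resampling-based importance for the rank product.
#'
#' @param table The analyzed [CohortTable-class].
#' @param dcv The matching [DCVResult-class].
#' @return Submodel x analyte VIP matrix.
#' @export
submodelVIPs <- function(table, dcv) {
  stopifnot(is(table, "CohortTable"), is(dcv, "DCVResult"))
  X <- concentrations(table)
  rows <- list()
  for (r in seq_len(ncol(dcv@outerFolds))) {
    folds <- dcv@outerFolds[, r]
    for (f in seq_len(max(folds))) {
      tr <- which(folds != f)
      fit <- suppressWarnings(
        fitPLSDA(X[tr, , drop = FALSE], dcv@truth[tr],
                 nLV = dcv@chosenLV[f, r],
                 scaling = dcv@control$scaling))
      rows[[length(rows) + 1L]] <- computeVIP(fit)
    }
  }
  do.call(rbind, rows)
}

#' @describeIn SelectionResult-class Named VIP vector.
#' @export
setMethod("vipScores", "SelectionResult",
          function(x, ...) stats::setNames(x@vip, x@analytes))

#' @describeIn SelectionResult-class Named rank-product vector.
#' @export
setMethod("rankProducts", "SelectionResult",
          function(x, ...) stats::setNames(x@rp, x@analytes))

#' @describeIn SelectionResult-class Consensus top-k analyte set.
#' @export
setMethod("consensusBiomarkers", "SelectionResult",
          function(x, ...) x@consensus)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: ", length(object@analytes), " analytes | top-",
      object@k, " consensus (", length(object@consensus), "):\n", sep = "")
  for (a in object@consensus) cat("  -", a, "\n")
})

#' Selection result as a data.frame
#'
#' @param x A [SelectionResult-class].
#' @param ... Ignored.
#' @return data.frame with analyte, VIP, RP, both ranks and a consensus flag,
#'   ordered by RP rank.
#' @export
as.data.frame.SelectionResult <- function(x, ...) {
  df <- data.frame(analyte = x@analytes, vip = x@vip, vip_rank = x@vipRank,
                   rp = x@rp, rp_rank = x@rpRank,
                   consensus = x@analytes %in% x@consensus,
                   stringsAsFactors = FALSE)
  df[order(df$rp_rank), , drop = FALSE]
}
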