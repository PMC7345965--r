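#' @include permutation.R
NULL

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups. Uses exact enumeration
#' when the combined sample size is at most 12 and there are no ties,
#' otherwise the normal approximation with tie correction and continuity
#' correction (the behaviour of [stats::wilcox.test()], which backs this
#' wrapper).
#'
#' @param groupA,groupB Numeric vectors (each non-empty).
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) applies the size rule above.
#' @return List with `U` (statistic for `groupA`) and two-sided `p`.
#' @export
mannWhitneyU <- function(groupA, groupB, exact = NULL) {
  if (length(groupA) < 1L || length(groupB) < 1L)
    stop("both groups must be non-empty")
  if (is.null(exact)) exact <- (length(groupA) + length(groupB)) <= 12
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Welch two-sample t-test (two-sided)
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom. If
#' both groups have zero variance and equal means the test is vacuous and
#' `p = 1` is returned by convention (so permutation replicates never
#' crash on degenerate columns).
#'
#' @param groupA,groupB Numeric vectors with >= 2 values each.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
welchTTest <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(mean(groupA) - mean(groupB)),
                df = NA_real_, p = 0))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-analyte univariate group comparison table
#'
#' One row per analyte with group means and SDs plus a two-sided p-value.
#' By default every analyte is tested with the Mann-Whitney U test; with
#' `protocol = "normality-gated"` a Shapiro-Wilk test (alpha = 0.05, both
#' groups) routes normal-looking analytes to the Welch t-test instead. A
#' Benjamini-Hochberg adjusted column is appended as a supplementary aid;
#' the primary p-values are reported raw.
#'
#' @param table A [CohortTable-class].
#' @param protocol `"mann-whitney"` (default) or `"normality-gated"`.
#' @return data.frame with columns `analyte`, `mean_cnt`, `sd_cnt`,
#'   `mean_sf`, `sd_sf`, `p_value`, `test_used`, `p_adj_bh`, ordered as the
#'   panel.
#' @examples
#' cohort <- generateCohort(defaultCohortSpec(seed = 5))
#' head(univariateTable(cohort))
#' @export
univariateTable <- function(table,
                            protocol = c("mann-whitney", "normality-gated")) {
  protocol <- match.arg(protocol)
  stopifnot(is(table, "CohortTable"))
  X <- concentrations(table)
  y <- classCode(table)
  .checkBothClasses(y)
  rows <- lapply(colnames(X), function(nm) {
    sf <- X[y == 1, nm]
    cnt <- X[y == 0, nm]
    useT <- FALSE
    if (protocol == "normality-gated" &&
        length(unique(sf)) > 2 && length(unique(cnt)) > 2) {
      useT <- stats::shapiro.test(sf)$p.value > 0.05 &&
        stats::shapiro.test(cnt)$p.value > 0.05
    }
    res <- if (useT) welchTTest(sf, cnt) else mannWhitneyU(sf, cnt)
    data.frame(analyte = nm,
               mean_cnt = mean(cnt), sd_cnt = stats::sd(cnt),
               mean_sf = mean(sf), sd_sf = stats::sd(sf),
               p_value = res$p,
               test_used = if (useT) "t-test" else "Mann-Whitney",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
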