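#' @include univariate.R
NULL

#' Write the full results bundle
#'
#' Exports the numeric content of a complete run as plain CSV (each with a
#' units/semantics header comment) plus a JSON manifest: the discriminant
#' summary table (group means/SDs, p-values, VIP/RP ranks, consensus flag),
#' the per-repetition DCV rates and chosen LVs, the final-model score
#' coordinates (score-plot analogue), and the permutation null samples with
#' observed statistics and p-values. The manifest records the seed and
#' configuration but no timestamps, so identical runs produce byte-identical
#' artifacts.
#'
#' @param results Named list with elements `cohort` ([CohortTable-class]),
#'   `univariate` (data.frame), `dcv` ([DCVResult-class]), `selection`
#'   ([SelectionResult-class]), optionally `permutation`
#'   ([PermutationResult-class]) and `config` (list).
#' @param outdir Output directory (created if absent).
#' @return The manifest list, invisibly; also written to `manifest.json`.
#' @export
writeResultsBundle <- function(results, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create outdir: ", outdir)
  }
  files <- character()
  put <- function(df, name, comments) {
    path <- file.path(outdir, name)
    writeCommentedCSV(df, path, comments)
    files <<- c(files, name)
  }

  put(writeCohortCSVFrame(results$cohort), "cohort.csv",
      c("urinary amino acid concentrations, umol/L",
        "class: SF = stone former (positive class), CNT = control"))

  sel <- as.data.frame(results$selection)
  uni <- results$univariate
  disc <- merge(sel, uni, by = "analyte", sort = FALSE)
  disc <- disc[order(disc$rp_rank), ]
  put(disc, "discriminant_table.csv",
      c("per-analyte selection + univariate summary",
        "mean_*/sd_*: group mean and SD, umol/L; p_value: two-sided",
        "vip: variable importance in projection (final model)",
        "rp: rank product across DCV outer submodels (small = important)",
        "consensus: in the top-k of both rankings"))

  dcv <- results$dcv
  dcvRep <- data.frame(repetition = seq_along(outerAccuracy(dcv)),
                       outer_accuracy = outerAccuracy(dcv),
                       inner_accuracy = innerAccuracy(dcv),
                       sf_rate = dcv@sfRate, cnt_rate = dcv@cntRate)
  put(dcvRep, "dcv_repetitions.csv",
      c("per-repetition double cross-validation classification rates, %",
        "sf_rate/cnt_rate: per-class outer rates"))
  put(dcvSummary(dcv), "dcv_summary.csv",
      c("mean +/- SEM over repetitions, %"))

  final <- finalPLSDAModel(results$cohort, dcv)
  sc <- final@scores
  scoreDF <- data.frame(sample_id = rownames(concentrations(results$cohort)),
                        class = as.character(classLabels(results$cohort)),
                        sc[, seq_len(min(2L, ncol(sc))), drop = FALSE])
  names(scoreDF)[-(1:2)] <- paste0("LV", seq_len(ncol(scoreDF) - 2L))
  put(scoreDF, "scores.csv",
      c("final all-data PLS-DA model score coordinates (unitless)",
        paste0("model uses ", final@nLV, " latent variable(s)")))

  permBlock <- NULL
  if (!is.null(results$permutation)) {
    perm <- results$permutation
    put(nullDistributions(perm), "permutation_null.csv",
        c("permutation null samples: one row per label permutation",
          "nmc: misclassification count; auroc, dq2: unitless"))
    permBlock <- list(nPermutations = perm@nPermutations,
                      observed = as.list(observedStatistics(perm)),
                      pValues = as.list(pValues(perm)))
  }

  manifest <- list(
    package = "aastone",
    version = as.character(utils::packageVersion("aastone")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    config = results$config,
    permutation = permBlock,
    files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Cohort as the tidy data.frame written by writeCohortCSV().
writeCohortCSVFrame <- function(table) {
  X <- concentrations(table)
  data.frame(sample_id = rownames(X),
             class = as.character(classLabels(table)),
             X, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the complete discovery pipeline
#'
#' Orchestrates the full strategy in order: cohort (simulated or supplied)
#' -> univariate comparisons -> repeated double cross-validated PLS-DA ->
#' VIP/RP biomarker selection -> permutation significance -> results bundle.
#' A single root seed is fanned out per stage (cohort, DCV and permutation
#' streams are derived from it by stage name), so any stage can be re-run in
#' isolation and the whole run is bitwise reproducible.
#'
#' @param cohort A [CohortTable-class], or a [CohortSpec-class] to simulate
#'   from (default: [defaultCohortSpec()]).
#' @param control [dcvControl()] settings.
#' @param nPermutations Label permutations for the significance stage; 0
#'   skips the stage.
#' @param topK Consensus cutoff for biomarker selection.
#' @param outdir Output directory for [writeResultsBundle()]; `NULL` skips
#'   writing.
#' @param seed Root seed.
#' @param verbose Print per-stage progress and timings.
#' @return Named list with `cohort`, `univariate`, `dcv`, `selection`,
#'   `permutation` (or `NULL`), `config`, and `manifest` when `outdir` is
#'   given.
#' @export
runFullAnalysis <- function(cohort = defaultCohortSpec(),
                            control = dcvControl(),
                            nPermutations = 1000L, topK = 9L,
                            outdir = NULL, seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  if (is(cohort, "CohortSpec")) {
    cohort <- stage("simulate",
                    generateCohort(cohort, seed = deriveSeed(seed, "cohort")))
  }
  stopifnot(is(cohort, "CohortTable"))
  uni <- stage("univariate", univariateTable(cohort))
  dcv <- stage("dcv", doubleCrossValidate(cohort, control,
                                          seed = deriveSeed(seed, "dcv")))
  sel <- stage("selection", selectBiomarkers(cohort, dcv, k = topK))
  perm <- if (nPermutations > 0) {
    stage("permutation",
          permutationNull(cohort, control, nPermutations = nPermutations,
                          seed = deriveSeed(seed, "permutation")))
  } else {
    say("[permutation] skipped (nPermutations = 0)")
    NULL
  }
  config <- list(seed = seed, control = unclass(control),
                 nPermutations = nPermutations, topK = topK,
                 permutationSkipped = is.null(perm))
  results <- list(cohort = cohort, univariate = uni, dcv = dcv,
                  selection = sel, permutation = perm, config = config)
  if (!is.null(outdir)) {
    results$manifest <- stage("report", writeResultsBundle(results, outdir))
  }
  invisible(results)
}
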