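#' @include cohort-spec.R
NULL

#' Class "CohortTable": a samples-by-analytes concentration table with labels
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"concentrations"` (analytes as rows, samples as columns, umol/L)
#' and a two-level class factor (`CNT` = control, `SF` = stone former) in
#' `colData`. All analysis entry points require both classes to be present;
#' SF is the positive class (coded 1) throughout.
#'
#' @section Accessors:
#' * `concentrations(x, samplesAsRows = TRUE)` — the numeric matrix; by
#'   default in the samples x analytes orientation used by the classifier.
#' * `classLabels(x)` — factor with levels `CNT`, `SF`.
#' * `classCode(x)` — numeric 0/1 coding (SF = 1).
#' * `analyteNames(x)` — panel names in order.
#'
#' @seealso [generateCohort()], [readCohortCSV()], [doubleCrossValidate()]
#' @name CohortTable-class
#' @exportClass CohortTable
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
  if (!"concentrations" %in% SummarizedExperiment::assayNames(object))
    return("assay 'concentrations' is required")
  m <- SummarizedExperiment::assay(object, "concentrations")
  if (!is.numeric(m)) return("concentrations must be numeric")
  if (any(!is.finite(m))) return("concentrations must be finite (no NA)")
  if (any(m < 0)) return("concentrations must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!"class" %in% names(cd)) return("colData column 'class' is required")
  cl <- cd$class
  if (!is.factor(cl) || !identical(levels(cl), c("CNT", "SF")))
    return("'class' must be a factor with levels CNT, SF")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample ids must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("analyte names must be present and unique")
  TRUE
})

#' Construct a CohortTable
#'
#' @param X Numeric samples x analytes concentration matrix (umol/L) with
#'   column names; or analytes x samples with `samplesAsRows = FALSE`.
#' @param classes Character/factor vector of `"CNT"`/`"SF"` labels, one per
#'   sample.
#' @param sampleIds Optional sample identifiers (default: rownames of `X` or
#'   `S1, S2, ...`).
#' @param samplesAsRows Orientation of `X` (default `TRUE`).
#' @return A [CohortTable-class].
#' @export
CohortTable <- function(X, classes, sampleIds = NULL, samplesAsRows = TRUE) {
  X <- as.matrix(X)
  if (samplesAsRows) X <- t(X)
  if (is.null(sampleIds)) {
    sampleIds <- colnames(X)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(X)))
  }
  colnames(X) <- sampleIds
  classes <- factor(as.character(classes), levels = c("CNT", "SF"))
  if (anyNA(classes)) stop("class labels must be 'CNT' or 'SF'")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentrations = X),
    colData = S4Vectors::DataFrame(class = classes, row.names = sampleIds))
  new("CohortTable", se)
}

#' @describeIn CohortTable-class Concentration matrix.
#' @param samplesAsRows Return samples x analytes (`TRUE`, default) or the
#'   stored analytes x samples assay.
#' @export
setMethod("concentrations", "CohortTable",
  function(x, samplesAsRows = TRUE, ...) {
    m <- SummarizedExperiment::assay(x, "concentrations")
    if (samplesAsRows) t(m) else m
  })

#' @describeIn CohortTable-class Class label factor (levels `CNT`, `SF`).
#' @export
setMethod("classLabels", "CohortTable",
  function(x, ...) SummarizedExperiment::colData(x)$class)

#' @describeIn CohortTable-class Analyte names in panel order.
#' @export
setMethod("analyteNames", "CohortTable", function(x, ...) rownames(x))

#' Numeric 0/1 class coding (SF = 1, CNT = 0)
#'
#' @param x A [CohortTable-class].
#' @return Numeric vector of 0/1, one per sample.
#' @export
classCode <- function(x) {
  as.numeric(classLabels(x) == "SF")
}

setMethod("show", "CohortTable", function(object) {
  cl <- classLabels(object)
  cat("CohortTable:", ncol(object), "samples x", nrow(object), "analytes |",
      sum(cl == "SF"), "SF /", sum(cl == "CNT"), "CNT (umol/L)\n")
})

.checkBothClasses <- function(y) {
  if (length(unique(y)) < 2L)
    stop("both classes (SF and CNT) must be present")
  invisible(TRUE)
}

#' Read a cohort from a tidy CSV file
#'
#' Expects a header row with a sample id column, a label column, and one
#' numeric column per analyte (umol/L). Lines starting with `#` are treated
#' as comments. Analyte column order is preserved.
#'
#' @param path CSV file path.
#' @param labelColumn Name of the class label column (default `"class"`).
#' @param idColumn Name of the sample id column (default `"sample_id"`).
#' @param labelMap Named character vector mapping file label values to the
#'   canonical levels, e.g. `c(control = "CNT", case = "SF")`. Defaults to
#'   identity on `CNT`/`SF`.
#' @return A [CohortTable-class].
#' @export
readCohortCSV <- function(path, labelColumn = "class",
                          idColumn = "sample_id",
                          labelMap = c(CNT = "CNT", SF = "SF")) {
  df <- readCommentedCSV(path)
  for (col in c(idColumn, labelColumn)) {
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  }
  ids <- as.character(df[[idColumn]])
  if (anyDuplicated(ids))
    stop("duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.character(df[[labelColumn]])
  if (!all(raw %in% names(labelMap)))
    stop("label values outside labelMap: ",
         paste(setdiff(unique(raw), names(labelMap)), collapse = ", "))
  classes <- unname(labelMap[raw])
  .checkBothClasses(classes)
  acols <- setdiff(names(df), c(idColumn, labelColumn))
  unknown <- setdiff(acols, .AA_PANEL)
  if (length(unknown))
    warning("analyte name(s) outside the default panel: ",
            paste(unknown, collapse = ", "))
  X <- matrix(NA_real_, nrow(df), length(acols),
              dimnames = list(ids, acols))
  for (j in seq_along(acols)) {
    v <- df[[acols[j]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad))
      stop("non-numeric concentration at row ", bad[1],
           ", column '", acols[j], "'")
    if (anyNA(num))
      stop("missing concentration at row ", which(is.na(num))[1],
           ", column '", acols[j], "'")
    X[, j] <- num
  }
  CohortTable(X, classes, sampleIds = ids)
}

#' Write a cohort to a tidy CSV file
#'
#' Columns: `sample_id`, `class`, then one column per analyte. A header
#' comment documents the units.
#'
#' @param table A [CohortTable-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortCSV <- function(table, path) {
  stopifnot(is(table, "CohortTable"))
  X <- concentrations(table)
  df <- data.frame(sample_id = rownames(X),
                   class = as.character(classLabels(table)),
                   X, check.names = FALSE, stringsAsFactors = FALSE)
  writeCommentedCSV(df, path, comments = c(
    "urinary amino acid concentrations, umol/L",
    "class: SF = stone former (positive class), CNT = control"))
}
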