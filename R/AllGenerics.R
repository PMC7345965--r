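#' @include utils.R
NULL

#' Accessors for cohort and result objects
#'
#' Small generic vocabulary shared by the S4 classes in this package:
#' cohort containers ([CohortTable-class], [CohortSpec-class]) and result
#' objects ([DCVResult-class], [SelectionResult-class],
#' [PermutationResult-class]).
#'
#' @param x,object An object of the documented class.
#' @param ... Passed to methods.
#' @return See the individual methods.
#' @name aastone-generics
NULL

#' @rdname aastone-generics
#' @export
setGeneric("analyteNames", function(x, ...) standardGeneric("analyteNames"))

#' @rdname aastone-generics
#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @rdname aastone-generics
#' @export
setGeneric("concentrations", function(x, ...) standardGeneric("concentrations"))

#' @rdname aastone-generics
#' @export
setGeneric("outerAccuracy", function(x, ...) standardGeneric("outerAccuracy"))

#' @rdname aastone-generics
#' @export
setGeneric("innerAccuracy", function(x, ...) standardGeneric("innerAccuracy"))

#' @rdname aastone-generics
#' @export
setGeneric("chosenLV", function(x, ...) standardGeneric("chosenLV"))

#' @rdname aastone-generics
#' @export
setGeneric("dcvSummary", function(x, ...) standardGeneric("dcvSummary"))

#' @rdname aastone-generics
#' @export
setGeneric("vipScores", function(x, ...) standardGeneric("vipScores"))

#' @rdname aastone-generics
#' @export
setGeneric("rankProducts", function(x, ...) standardGeneric("rankProducts"))

#' @rdname aastone-generics
#' @export
setGeneric("consensusBiomarkers",
           function(x, ...) standardGeneric("consensusBiomarkers"))

#' @rdname aastone-generics
#' @export
setGeneric("nullDistributions",
           function(x, ...) standardGeneric("nullDistributions"))

#' @rdname aastone-generics
#' @export
setGeneric("observedStatistics",
           function(x, ...) standardGeneric("observedStatistics"))

#' @rdname aastone-generics
#' @export
setGeneric("pValues", function(x, ...) standardGeneric("pValues"))
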