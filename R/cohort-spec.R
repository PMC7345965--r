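#' @include AllGenerics.R
NULL

# 35-analyte urinary amino acid panel (ASCII names; Greek prefixes spelled out).
.AA_PANEL <- c(
  "alanine", "alpha-aminobutyric acid", "aminoadipic acid", "anserine",
  "arginine", "asparagine", "aspartic acid", "beta-alanine",
  "beta-aminobutyric acid", "carnosine", "citrulline", "cystine",
  "ethanolamine", "gamma-aminobutyric acid", "glycine", "glutamic acid",
  "histidine", "isoleucine", "4-hydroxyproline", "leucine", "lysine",
  "methionine", "1-methylhistidine", "3-methylhistidine", "ornithine",
  "phenylalanine", "phosphoethanolamine", "proline", "sarcosine", "serine",
  "taurine", "threonine", "tryptophan", "tyrosine", "valine"
)

# Published group summaries (mean, SD; umol/L) for the nine analytes found to
# discriminate stone formers (all lower in SF) from controls.
.DISCRIMINANT_PARAMS <- data.frame(
  name = c("alpha-aminobutyric acid", "asparagine", "ethanolamine",
           "isoleucine", "methionine", "phenylalanine", "serine",
           "tryptophan", "valine"),
  meanCNT = c(14.0, 214.5, 365.4, 9.9, 8.2, 49.5, 354.1, 61.2, 34.4),
  sdCNT   = c(5.8, 73.2, 69.9, 3.7, 2.8, 13.2, 109.0, 14.3, 12.0),
  meanSF  = c(6.1, 71.4, 215.3, 4.2, 2.7, 24.7, 105.6, 33.5, 15.2),
  sdSF    = c(2.5, 44.0, 87.6, 3.8, 2.7, 15.4, 93.8, 21.5, 11.4),
  stringsAsFactors = FALSE
)

# Physiologically plausible urinary levels for the 26 analytes with no group
# difference (no published per-subject values exist; these are generator
# defaults with identical CNT and SF distributions, overridable by the user).
.NULL_ANALYTE_PARAMS <- data.frame(
  name = c("alanine", "aminoadipic acid", "anserine", "arginine",
           "aspartic acid", "beta-alanine", "beta-aminobutyric acid",
           "carnosine", "citrulline", "cystine", "gamma-aminobutyric acid",
           "glycine", "glutamic acid", "histidine", "4-hydroxyproline",
           "leucine", "lysine", "1-methylhistidine", "3-methylhistidine",
           "ornithine", "phosphoethanolamine", "proline", "sarcosine",
           "taurine", "threonine", "tyrosine"),
  mean = c(230, 35, 12, 20, 15, 18, 10, 25, 9, 45, 6, 900, 30, 650, 14,
           25, 120, 180, 160, 15, 40, 12, 5, 450, 90, 60),
  sd   = c(90, 15, 6, 9, 7, 8, 5, 12, 4, 18, 3, 320, 13, 210, 7,
           10, 60, 90, 70, 7, 18, 6, 2.5, 220, 35, 25),
  stringsAsFactors = FALSE
)

#' Class "CohortSpec": parameterization of a synthetic case-control cohort
#'
#' Holds per-analyte group distribution parameters (arithmetic mean and SD of
#' urinary concentration, umol/L), the group sizes, the positive-support
#' sampling distribution and the root seed. [generateCohort()] turns a spec
#' into a [CohortTable-class].
#'
#' @slot analytes `data.frame` with columns `name`, `meanCNT`, `sdCNT`,
#'   `meanSF`, `sdSF`, `discriminant` (one row per analyte; means strictly
#'   positive, SDs non-negative; `sd = 0` produces a constant column).
#' @slot nSF,nCNT Integer group sizes (stone formers / controls), each >= 2.
#' @slot distribution `"lognormal"` (closed-form moment matching) or
#'   `"truncnorm"` (zero-truncated normal, numerically moment-corrected).
#'   The truncated-normal family cannot reach coefficients of variation
#'   above ~0.95; such analytes fall back to the lognormal marginal.
#' @slot rho Equicorrelation of analytes on the latent Gaussian scale
#'   (0 = independent columns, the default).
#' @slot seed Integer root seed; per-analyte, per-group streams are derived
#'   from it by hashing the analyte name, so extending the panel never
#'   perturbs existing columns.
#'
#' @seealso [defaultCohortSpec()], [generateCohort()], [sampleAnalyte()]
#' @name CohortSpec-class
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(analytes = "data.frame", nSF = "integer", nCNT = "integer",
                 distribution = "character", rho = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  a <- object@analytes
  needed <- c("name", "meanCNT", "sdCNT", "meanSF", "sdSF", "discriminant")
  if (!all(needed %in% names(a)))
    return(paste("analytes must have columns:", paste(needed, collapse = ", ")))
  if (anyDuplicated(a$name)) return("duplicated analyte names")
  num <- as.matrix(a[, c("meanCNT", "sdCNT", "meanSF", "sdSF")])
  if (any(!is.finite(num))) return("non-finite analyte parameters")
  if (any(a$meanCNT <= 0) || any(a$meanSF <= 0))
    return("analyte means must be strictly positive")
  if (any(a$sdCNT < 0) || any(a$sdSF < 0))
    return("analyte SDs must be non-negative")
  if (object@nSF < 2L || object@nCNT < 2L)
    return("each group needs at least 2 samples")
  if (!object@distribution %in% c("lognormal", "truncnorm"))
    return("distribution must be 'lognormal' or 'truncnorm'")
  if (object@rho < 0 || object@rho >= 1)
    return("rho must be in [0, 1)")
  TRUE
})

#' Construct a synthetic cohort specification
#'
#' @param analytes `data.frame` with columns `name`, `meanCNT`, `sdCNT`,
#'   `meanSF`, `sdSF` and logical `discriminant`.
#' @param nSF,nCNT Number of stone-former (case) and control samples.
#' @param distribution Sampling family, `"lognormal"` or `"truncnorm"`.
#' @param rho Latent-scale equicorrelation between analytes (default 0).
#' @param seed Integer root seed.
#' @return A [CohortSpec-class] object.
#' @export
CohortSpec <- function(analytes, nSF, nCNT, distribution = "lognormal",
                       rho = 0, seed = 1L) {
  new("CohortSpec", analytes = analytes, nSF = as.integer(nSF),
      nCNT = as.integer(nCNT), distribution = distribution,
      rho = as.numeric(rho), seed = as.integer(seed))
}

#' Default cohort specification from the published group summaries
#'
#' Builds the study-sized specification: 15 stone formers and 12 controls over
#' the 35-analyte urinary amino acid panel. The nine discriminant analytes
#' (alpha-aminobutyric acid, asparagine, ethanolamine, isoleucine, methionine,
#' phenylalanine, serine, tryptophan, valine) carry the published group means
#' and SDs, all lower in stone formers; the remaining 26 analytes get
#' identical CNT and SF distributions at physiologically plausible urinary
#' levels.
#'
#' @inheritParams CohortSpec
#' @param nullAnalytes Optional `data.frame` with columns `name`, `mean`, `sd`
#'   overriding the default parameters of the 26 non-discriminant analytes.
#' @return A [CohortSpec-class] with 35 analytes, `nSF = 15`, `nCNT = 12`.
#' @examples
#' spec <- defaultCohortSpec(seed = 7)
#' sum(analyteParams(spec)$discriminant)  # 9
#' @export
defaultCohortSpec <- function(nSF = 15L, nCNT = 12L,
                              distribution = "lognormal", rho = 0, seed = 1L,
                              nullAnalytes = NULL) {
  nulls <- .NULL_ANALYTE_PARAMS
  if (!is.null(nullAnalytes)) {
    stopifnot(all(c("name", "mean", "sd") %in% names(nullAnalytes)))
    idx <- match(nullAnalytes$name, nulls$name)
    if (anyNA(idx)) stop("unknown null analyte name(s): ",
                         paste(nullAnalytes$name[is.na(idx)], collapse = ", "))
    nulls$mean[idx] <- nullAnalytes$mean
    nulls$sd[idx] <- nullAnalytes$sd
  }
  disc <- .DISCRIMINANT_PARAMS
  rows <- lapply(.AA_PANEL, function(nm) {
    if (nm %in% disc$name) {
      d <- disc[disc$name == nm, ]
      data.frame(name = nm, meanCNT = d$meanCNT, sdCNT = d$sdCNT,
                 meanSF = d$meanSF, sdSF = d$sdSF, discriminant = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      d <- nulls[nulls$name == nm, ]
      data.frame(name = nm, meanCNT = d$mean, sdCNT = d$sd,
                 meanSF = d$mean, sdSF = d$sd, discriminant = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  CohortSpec(do.call(rbind, rows), nSF = nSF, nCNT = nCNT,
             distribution = distribution, rho = rho, seed = seed)
}

#' Per-analyte parameters of a cohort specification
#'
#' @param spec A [CohortSpec-class].
#' @return The `analytes` parameter `data.frame`.
#' @export
analyteParams <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  spec@analytes
}

#' @describeIn CohortSpec-class Analyte names, in panel order.
#' @export
setMethod("analyteNames", "CohortSpec", function(x, ...) x@analytes$name)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", nrow(object@analytes), "analytes |",
      object@nSF, "SF +", object@nCNT, "CNT |",
      sum(object@analytes$discriminant), "discriminant\n")
  cat("  distribution:", object@distribution,
      "| rho:", object@rho, "| seed:", object@seed, "\n")
})

#' Read / write a cohort specification as JSON
#'
#' Serializes all generator parameters (analyte table, group sizes,
#' distribution family, correlation, seed) so a simulation is fully
#' reproducible from its config file.
#'
#' @param spec A [CohortSpec-class].
#' @param path File path of the JSON config.
#' @return `writeCohortSpec` returns `path` invisibly; `readCohortSpec`
#'   returns a [CohortSpec-class].
#' @export
writeCohortSpec <- function(spec, path) {
  stopifnot(is(spec, "CohortSpec"))
  jsonlite::write_json(
    list(analytes = spec@analytes, nSF = spec@nSF, nCNT = spec@nCNT,
         distribution = spec@distribution, rho = spec@rho, seed = spec@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  CohortSpec(as.data.frame(x$analytes), nSF = x$nSF, nCNT = x$nCNT,
             distribution = x$distribution, rho = x$rho, seed = x$seed)
}
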