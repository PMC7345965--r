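#' @include cohort-table.R
NULL

# --- moment matching -------------------------------------------------------

# Lognormal parameters with arithmetic mean m and SD s (exact closed form).
.lognormalParams <- function(m, s) {
  sigma2 <- log1p((s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Moments of a normal(mu, sigma) truncated to (0, Inf).
.truncnormMoments <- function(mu, sigma) {
  alpha <- -mu / sigma
  Z <- stats::pnorm(alpha, lower.tail = FALSE)
  lambda <- stats::dnorm(alpha) / Z
  mean <- mu + sigma * lambda
  v <- sigma^2 * (1 + alpha * lambda - lambda^2)
  list(mean = mean, sd = sqrt(pmax(v, 0)))
}

# Solve for (mu, sigma) of the parent normal so the zero-truncated
# distribution has arithmetic mean m and SD s. Naive truncation of N(m, s)
# biases low-mean/high-CV analytes upward, so the correction is numeric:
# the truncated CV is a monotone function of alpha = -mu/sigma alone, so a
# root search in alpha followed by a scale factor matches both moments.
# The family's CV is bounded (~0.98 as alpha -> Inf); targets above 0.95
# are out of numerically safe reach and return NULL (the caller falls back
# to the lognormal marginal for that analyte).
.truncnormParams <- function(m, s) {
  if (s / m > 0.95) return(NULL)
  cvGap <- function(a) {
    mo <- .truncnormMoments(-a, 1)  # alpha = a at unit sigma
    mo$sd / mo$mean - s / m
  }
  a <- stats::uniroot(cvGap, c(-40, 6.5), tol = 1e-12)$root
  mo <- .truncnormMoments(-a, 1)
  sigma <- m / mo$mean
  list(mu = -a * sigma, sigma = sigma)
}

# Map standard-normal draws z to the moment-matched positive marginal.
.zToConcentration <- function(z, m, s, distribution) {
  if (s == 0) return(rep(m, length(z)))
  p <- if (distribution == "truncnorm") .truncnormParams(m, s) else NULL
  if (is.null(p)) {  # lognormal, also the high-CV truncnorm fallback
    lp <- .lognormalParams(m, s)
    exp(lp$mu + lp$sigma * z)
  } else {
    p0 <- stats::pnorm(-p$mu / p$sigma)
    p$mu + p$sigma * stats::qnorm(p0 + stats::pnorm(z) * (1 - p0))
  }
}

# --- sampling --------------------------------------------------------------

.groupParams <- function(spec, analyte, group) {
  a <- spec@analytes
  i <- match(analyte, a$name)
  if (is.na(i)) stop("unknown analyte: ", analyte)
  if (group == "SF") list(m = a$meanSF[i], s = a$sdSF[i])
  else list(m = a$meanCNT[i], s = a$sdCNT[i])
}

#' Draw synthetic concentrations for one analyte and group
#'
#' Samples `n` i.i.d. values from the positive-support distribution
#' moment-matched to the spec's (mean, SD) for that analyte and group. Uses
#' the same per-analyte random stream as [generateCohort()] (derived from the
#' root seed and the analyte name), so marginal draws reproduce the cohort
#' generator's behaviour.
#'
#' @param spec A [CohortSpec-class].
#' @param analyte Analyte name (must be in the spec panel).
#' @param group `"CNT"` or `"SF"`.
#' @param n Number of draws.
#' @param seed Root seed; defaults to the spec seed.
#' @return Numeric vector of `n` strictly positive concentrations (umol/L).
#' @examples
#' spec <- defaultCohortSpec(seed = 1)
#' mean(sampleAnalyte(spec, "serine", "CNT", 1000))
#' @export
sampleAnalyte <- function(spec, analyte, group = c("CNT", "SF"), n,
                          seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  group <- match.arg(group)
  if (is.null(seed)) seed <- spec@seed
  p <- .groupParams(spec, analyte, group)
  z <- withSeed(deriveSeed(seed, paste0(group, "::", analyte)),
                stats::rnorm(n))
  .zToConcentration(z, p$m, p$s, spec@distribution)
}

#' Generate a synthetic case-control cohort
#'
#' Draws a `(nSF + nCNT) x analytes` table of strictly positive urinary
#' concentrations from the spec's moment-matched marginals. Each analyte and
#' group has its own random stream derived from the root seed and the analyte
#' name, so the same seed always reproduces the same table and adding
#' analytes to a spec leaves existing columns untouched. With `rho > 0`,
#' analytes share a per-sample latent Gaussian factor (equicorrelation rho)
#' before the marginal transform, emulating the correlated panels PLS-DA is
#' designed for.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Optional root seed overriding the spec seed.
#' @return A [CohortTable-class] with samples `SF1..`, `CNT1..`.
#' @examples
#' cohort <- generateCohort(defaultCohortSpec(seed = 42))
#' cohort
#' @export
generateCohort <- function(spec, seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  methods::validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  groups <- list(SF = spec@nSF, CNT = spec@nCNT)
  rho <- spec@rho
  blocks <- lapply(names(groups), function(g) {
    n <- groups[[g]]
    shared <- if (rho > 0) {
      withSeed(deriveSeed(seed, paste0("shared::", g)), stats::rnorm(n))
    } else NULL
    cols <- vapply(spec@analytes$name, function(nm) {
      p <- .groupParams(spec, nm, g)
      e <- withSeed(deriveSeed(seed, paste0(g, "::", nm)), stats::rnorm(n))
      z <- if (rho > 0) sqrt(rho) * shared + sqrt(1 - rho) * e else e
      .zToConcentration(z, p$m, p$s, spec@distribution)
    }, numeric(n))
    rownames(cols) <- paste0(g, seq_len(n))
    cols
  })
  X <- do.call(rbind, blocks)
  classes <- rep(names(groups), times = unlist(groups))
  CohortTable(X, classes, sampleIds = rownames(X))
}
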