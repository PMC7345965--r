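test_that("default spec encodes the published panel and group structure", {
  spec <- defaultCohortSpec()
  a <- analyteParams(spec)
  expect_equal(nrow(a), 35)
  expect_equal(spec@nSF, 15L)
  expect_equal(spec@nCNT, 12L)
  expect_equal(sum(a$discriminant), 9)
  ser <- a[a$name == "serine", ]
  expect_equal(ser$meanCNT, 354.1)
  expect_equal(ser$sdCNT, 109.0)
  expect_equal(ser$meanSF, 105.6)
  expect_equal(ser$sdSF, 93.8)
  aab <- a[a$name == "alpha-aminobutyric acid", ]
  expect_equal(unlist(aab[c("meanCNT", "sdCNT", "meanSF", "sdSF")],
                      use.names = FALSE), c(14.0, 5.8, 6.1, 2.5))
  # every discriminant analyte is lower in stone formers
  expect_true(all(a$meanSF[a$discriminant] < a$meanCNT[a$discriminant]))
  # null analytes have identical group distributions
  expect_true(all(a$meanSF[!a$discriminant] == a$meanCNT[!a$discriminant]))
})

test_that("spec validation rejects bad parameterizations", {
  a <- analyteParams(defaultCohortSpec())
  bad <- a; bad$meanSF[1] <- -1
  expect_error(CohortSpec(bad, 15, 12), "positive")
  bad <- a; bad$sdCNT[3] <- -0.1
  expect_error(CohortSpec(bad, 15, 12), "non-negative")
  expect_error(CohortSpec(a, 1, 12), "at least 2")
  expect_error(CohortSpec(a[c(1, 1), ], 15, 12), "duplicated")
})

test_that("generator recovers the specified moments for every analyte and group", {
  for (distribution in c("lognormal", "truncnorm")) {
    spec <- defaultCohortSpec(seed = 101, distribution = distribution)
    a <- analyteParams(spec)
    for (i in seq_len(nrow(a))) {
      for (g in c("CNT", "SF")) {
        m <- if (g == "CNT") a$meanCNT[i] else a$meanSF[i]
        s <- if (g == "CNT") a$sdCNT[i] else a$sdSF[i]
        x <- sampleAnalyte(spec, a$name[i], g, n = 10000)
        expect_lt(abs(mean(x) - m), 4 * s / sqrt(10000))
        expect_lt(abs(sd(x) - s) / s, 0.10)
        expect_gt(min(x), 0)
      }
    }
  }
})

test_that("truncated-normal parameters are numerically moment-corrected", {
  # naive truncation of N(m, s) at zero biases a low-mean, high-CV analyte
  # (asparagine SF: 71.4 +/- 44.0) upward by several percent
  m <- 71.4; s <- 44.0
  set.seed(1)
  naive <- rnorm(2e5, m, s)
  naive <- naive[naive > 0]
  expect_gt(mean(naive), m * 1.03)
  spec <- defaultCohortSpec(seed = 5, distribution = "truncnorm")
  x <- sampleAnalyte(spec, "asparagine", "SF", n = 20000)
  expect_lt(abs(mean(x) - m) / m, 0.02)
  expect_lt(abs(sd(x) - s) / s, 0.05)
})

test_that("same spec and seed reproduce the identical table", {
  spec <- defaultCohortSpec(seed = 7)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(concentrations(c1), concentrations(c2))
  c3 <- generateCohort(spec, seed = 8)
  expect_false(identical(concentrations(c1), concentrations(c3)))
})

test_that("zero-SD analytes generate constant columns at their mean", {
  a <- analyteParams(defaultCohortSpec())
  a$sdCNT[a$name == "glycine"] <- 0
  a$sdSF[a$name == "glycine"] <- 0
  spec <- CohortSpec(a, 15, 12, seed = 3L)
  X <- concentrations(generateCohort(spec))
  expect_true(all(X[, "glycine"] == 900))
})

test_that("discriminant analytes come out lower in stone formers", {
  spec <- defaultCohortSpec(nSF = 1000, nCNT = 1000, seed = 11)
  co <- generateCohort(spec)
  X <- concentrations(co)
  y <- classCode(co)
  a <- analyteParams(spec)
  for (nm in a$name[a$discriminant]) {
    expect_lt(mean(X[y == 1, nm]), mean(X[y == 0, nm]))
  }
})

test_that("per-analyte streams are stable under panel changes", {
  spec <- defaultCohortSpec(seed = 9)
  a <- analyteParams(spec)
  sub <- CohortSpec(a[1:10, ], 15, 12, seed = 9L)
  Xfull <- concentrations(generateCohort(spec))
  Xsub <- concentrations(generateCohort(sub))
  expect_identical(Xfull[, a$name[1:10]], Xsub)
})

test_that("equicorrelation induces positive within-group correlations", {
  # correlations computed within the control group so the class effect
  # cannot masquerade as analyte correlation
  cntCors <- function(rho) {
    spec <- defaultCohortSpec(nSF = 400, nCNT = 400, seed = 21, rho = rho)
    co <- generateCohort(spec)
    X <- concentrations(co)[classCode(co) == 0, 1:8]
    cor(X)[upper.tri(diag(8))]
  }
  expect_gt(median(cntCors(0.6)), 0.3)
  expect_lt(max(abs(cntCors(0))), 0.2)
})

test_that("cohort spec survives a JSON round trip", {
  spec <- defaultCohortSpec(seed = 13, distribution = "truncnorm", rho = 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  writeCohortSpec(spec, path)
  back <- readCohortSpec(path)
  expect_equal(analyteParams(back), analyteParams(spec))
  expect_identical(concentrations(generateCohort(back)),
                   concentrations(generateCohort(spec)))
})
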