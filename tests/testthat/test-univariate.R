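test_that("exact Mann-Whitney matches full enumeration under separation", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)  # 2 / choose(6, 3) tail
  expect_equal(res$p, enumerateMWPValue(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$U, 0)
})

test_that("Mann-Whitney is symmetric and flat for identical groups", {
  a <- c(5, 9, 2, 7); b <- c(1, 8, 4, 6, 3)
  expect_equal(mannWhitneyU(a, b)$p, mannWhitneyU(b, a)$p)
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3), exact = FALSE)
  expect_equal(same$U, 9 / 2)  # n^2 / 2 with all ranks tied
  expect_gte(same$p, 0.9)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate Mann-Whitney agree at moderate n", {
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(12, mean = runif(1, 0, 1.5))
    pe <- mannWhitneyU(a, b, exact = TRUE)$p
    pa <- mannWhitneyU(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Welch t-test matches the closed-form summary-statistic oracle", {
  # construct samples with exactly the published group summaries
  exactMoments <- function(n, m, s) {
    x <- scale(seq_len(n))  # mean 0, sd 1
    m + s * as.numeric(x)
  }
  a <- exactMoments(12, 14.0, 5.8)   # control-style group
  b <- exactMoments(15, 6.1, 2.5)    # stone-former-style group
  res <- welchTTest(a, b)
  se <- sqrt(5.8^2 / 12 + 2.5^2 / 15)
  tOracle <- (14.0 - 6.1) / se
  dfOracle <- se^4 / ((5.8^2 / 12)^2 / 11 + (2.5^2 / 15)^2 / 14)
  expect_equal(res$t, tOracle, tolerance = 1e-12)
  expect_equal(res$df, dfOracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-tOracle, dfOracle), tolerance = 1e-12)
  expect_lt(res$p, 0.001)
})

test_that("Welch t is location invariant and degenerate-safe", {
  set.seed(32)
  a <- rnorm(8); b <- rnorm(9, 1)
  expect_equal(welchTTest(a, b)$t, welchTTest(a + 100, b + 100)$t,
               tolerance = 1e-10)
  expect_equal(welchTTest(c(2, 2, 2), c(2, 2))$p, 1)
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("the univariate table reports every analyte with correct direction", {
  co <- generateCohort(defaultCohortSpec(seed = 5))
  tab <- univariateTable(co)
  expect_equal(nrow(tab), 35)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  planted <- plantedBiomarkers()
  sub <- tab[tab$analyte %in% planted, ]
  expect_true(all(sub$mean_sf < sub$mean_cnt))
  expect_true(all(sub$p_value < 0.05))
  expect_true(all(tab$test_used == "Mann-Whitney"))

  gated <- univariateTable(co, protocol = "normality-gated")
  expect_true(all(gated$test_used %in% c("t-test", "Mann-Whitney")))
})

test_that("permuted labels keep the per-analyte false-positive rate low", {
  co <- generateCohort(defaultCohortSpec(seed = 5))
  set.seed(77)
  frac <- replicate(5, {
    scrambled <- CohortTable(concentrations(co),
                             sample(as.character(classLabels(co))))
    mean(univariateTable(scrambled)$p_value < 0.05)
  })
  expect_lte(mean(frac), 0.20)
})

test_that("stronger group shifts never raise the median p-value", {
  pAt <- function(shift, seed) {
    a <- analyteParams(nullCohortSpec(seed = seed))
    a$meanSF <- a$meanCNT * (1 - shift)
    co <- generateCohort(CohortSpec(a, 15, 12, seed = as.integer(seed)))
    median(univariateTable(co)$p_value)
  }
  meds <- sapply(c(0, 0.3, 0.6), function(s) {
    median(sapply(1:10, function(seed) pAt(s, seed)))
  })
  expect_true(all(diff(meds) <= 0))
})
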