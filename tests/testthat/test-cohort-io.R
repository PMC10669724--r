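test_that("readCohort validates roles, ranges and round-trips", {
  d <- toy_cohort_df(3)
  p <- write_toy_csv(d)
  tab <- readCohort(p)
  expect_s3_class(tab, "CohortTable")
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "n_coerced"), 0L)

  # out-of-range age becomes missing with a warning count of 1
  d2 <- toy_cohort_df(3)
  d2$age[2] <- -1
  expect_warning(tab2 <- readCohort(write_toy_csv(d2)),
                 "out-of-range")
  expect_true(is.na(tab2$age[2]))
  expect_equal(attr(tab2, "n_coerced"), 1L)

  # missing required column is a schema error naming the role
  d3 <- toy_cohort_df(3)
  d3$reading <- NULL
  expect_error(readCohort(write_toy_csv(d3)), "reading")
  expect_error(readCohort(tempfile()), "not found")

  # schema mapping of non-canonical file headers
  d4 <- toy_cohort_df(4)
  names(d4)[names(d4) == "reading"] <- "score"
  tab4 <- readCohort(write_toy_csv(d4), schema = c(reading = "score"))
  expect_equal(tab4$reading, d4$score)

  # simulate -> write -> read round-trip preserves values
  sim <- simulateCohort(simulationDesign(n = 40), seed = 11)
  p5 <- tempfile(fileext = ".csv")
  writeCohort(sim, p5)
  back <- readCohort(p5, snps = attr(sim, "snps"))
  for (cl in c("gender", "age", "home_supervision", "reading",
               "rs11629841"))
    expect_equal(back[[cl]], sim[[cl]], tolerance = 1e-12)
  expect_true(file.exists(paste0(p5, ".truth.json")))
})

test_that("zscoreColumns standardizes exactly, idempotently, keeps NA", {
  d <- data.frame(a = c(1, 2, 3), b = c(5, NA, 9))
  z <- zscoreColumns(d, c("a", "b"))
  expect_equal(z$a, c(-1, 0, 1))
  expect_true(is.na(z$b[2]))
  expect_lt(abs(mean(z$b, na.rm = TRUE)), 1e-10)
  expect_lt(abs(sd(z$b, na.rm = TRUE) - 1), 1e-10)
  # idempotence
  z2 <- zscoreColumns(z, c("a", "b"))
  expect_equal(z2$a, z$a, tolerance = 1e-10)
  expect_equal(attr(z, "standardization")$mean[1], 2)
  # zero variance errors with the column name
  expect_error(zscoreColumns(data.frame(k = c(2, 2, 2)), "k"), "k")

  # n = 745 simulated home-supervision scores
  sim <- simulateCohort(simulationDesign(), seed = 5)
  zz <- zscoreColumns(as.data.frame(sim), "home_supervision")
  expect_lt(abs(mean(zz$home_supervision)), 1e-10)
  expect_lt(abs(sd(zz$home_supervision) - 1), 1e-10)
})

test_that("cronbachAlpha matches hand and simulation oracles", {
  # identical items -> alpha = 1
  m <- matrix(rep(c(1, 3, 5, 2, 4), 5), ncol = 5)
  expect_equal(cronbachAlpha(m), 1)

  # exact 2-item covariance [[1, .5], [.5, 1]]:
  # alpha = 2 * (1 - 2/3) = 2/3
  x <- with_exact_cov(50, matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(cronbachAlpha(x), 2 / 3, tolerance = 1e-10)

  # uncorrelated equal-variance items, large n -> alpha ~ 0
  set.seed(42)
  u <- matrix(rnorm(5 * 20000), ncol = 5)
  expect_lt(abs(cronbachAlpha(u)), 3 * 0.02)

  expect_error(cronbachAlpha(matrix(1, 5, 1)), "2 items")
  expect_error(cronbachAlpha(matrix(1, 10, 3)), "variance")
})

test_that("correlationReport matches t-distribution p-values and bounds", {
  set.seed(7)
  d <- data.frame(x = rnorm(30))
  d$y <- -d$x
  d$z <- rnorm(30)
  rep_ <- correlationReport(d, c("x", "y", "z"))
  expect_equal(rep_$r["x", "y"], -1)
  expect_equal(diag(rep_$r), c(x = 1, y = 1, z = 1))
  expect_true(all(rep_$r >= -1 & rep_$r <= 1))
  expect_equal(rep_$r, t(rep_$r))
  # p-value oracle via cor.test
  ct <- cor.test(d$x, d$z)
  expect_equal(rep_$p["x", "z"], ct$p.value, tolerance = 1e-12)

  # constant column flagged undefined
  d$k <- 1
  rep2 <- correlationReport(d, c("x", "k"))
  expect_true(rep2$undefined["x", "k"])

  # n = 745 bivariate at rho = 0.14: r within 3/sqrt(n) of truth
  set.seed(99)
  n <- 745; rho <- 0.14
  a <- rnorm(n); b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  r3 <- correlationReport(data.frame(a = a, b = b), c("a", "b"))
  expect_lt(abs(r3$r["a", "b"] - rho), 3 / sqrt(n))

  # on standardized variables the correlation equals the covariance
  zd <- zscoreColumns(data.frame(a = a, b = b), c("a", "b"))
  r4 <- correlationReport(zd, c("a", "b"))
  expect_equal(r4$r["a", "b"], cov(zd$a, zd$b), tolerance = 1e-12)
})

test_that("correlation report renders stars and writes CSV", {
  set.seed(3)
  d <- data.frame(x = rnorm(50))
  d$y <- d$x + rnorm(50, sd = 0.3)
  rep_ <- correlationReport(d, c("x", "y"))
  md <- formatCorrelationMarkdown(rep_)
  expect_true(any(grepl("\\*\\*", md)))  # strong correlation starred
  f <- tempfile(fileext = ".csv")
  writeCorrelationCsv(rep_, f)
  back <- utils::read.csv(f)
  expect_equal(back$x[2], rep_$r["y", "x"], tolerance = 1e-6)
})
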