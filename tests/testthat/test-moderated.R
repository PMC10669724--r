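test_that("fitOls recovers exact and noisy relations", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  f <- fitOls("y", "x", d)
  expect_equal(unname(f$coef[["x"]]), 2)
  expect_equal(f$r.squared, 1)

  # agreement with lm on a noisy problem, incl. covariance matrix
  set.seed(12)
  d2 <- data.frame(a = rnorm(80), b = rnorm(80))
  d2$y <- 1 + 0.5 * d2$a - 0.3 * d2$b + 0.2 * d2$a * d2$b + rnorm(80)
  f2 <- fitOls("y", c("a", "b", "a*b"), d2)
  l2 <- lm(y ~ a * b, data = d2)
  expect_equal(unname(f2$coef), unname(coef(l2)[c(1, 2, 3, 4)]),
               tolerance = 1e-10)
  expect_equal(unname(diag(f2$vcov)), unname(diag(vcov(l2))[c(1, 2, 3, 4)]),
               tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(cbind(1, d2$a, d2$b, d2$a * d2$b),
                              f2$residuals))), 1e-8 * nrow(d2))
  # standardized beta = b * sd(x) / sd(y), invariant to rescaling
  expect_equal(f2$beta[["a"]],
               f2$coef[["a"]] * sd(d2$a) / sd(d2$y), tolerance = 1e-12)
  d3 <- d2; d3$a <- d3$a * 100
  f3 <- fitOls("y", c("a", "b", "a*b"), d3)
  expect_equal(f3$beta[["a"]], f2$beta[["a"]], tolerance = 1e-10)

  expect_error(fitOls("y", c("a", "a"), d2), "duplicate")
  d2$a2 <- 2 * d2$a
  expect_error(fitOls("y", c("a", "a2"), d2), "collinear")
})

test_that("hierarchical blocks report dR2/dF consistent with manual fits", {
  set.seed(33)
  d <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
  d$y <- 0.4 * d$x1 + 0.3 * d$x2 + rnorm(100)
  h <- hierarchicalBlocks("y", list("x1", c("x1", "x2"),
                                    c("x1", "x2", "x3")), d)
  # manual two-step recomputation
  f1 <- fitOls("y", "x1", d); f2 <- fitOls("y", c("x1", "x2"), d)
  dR2 <- f2$r.squared - f1$r.squared
  dF <- dR2 / ((1 - f2$r.squared) / (100 - 2 - 1))
  expect_equal(h$steps$dR2[2], dR2, tolerance = 1e-10)
  expect_equal(h$steps$dF[2], dF, tolerance = 1e-10)
  # R^2 non-decreasing; dF of a single added term equals its t^2
  expect_true(all(diff(h$steps$r.squared) >= -1e-12))
  expect_equal(h$steps$dF[3], unname(h$fits[[3]]$t[["x3"]]^2),
               tolerance = 1e-8)
  # duplicate block contributes exactly zero
  h2 <- hierarchicalBlocks("y", list("x1", "x1"), d)
  expect_equal(h2$steps$dR2[2], 0)
  expect_error(hierarchicalBlocks("y", list(c("x1", "x2"), "x1"), d),
               "nested")
})

test_that("simple slopes match stratified refits", {
  d <- sim_analysis_frame(61)
  f <- fitOls("reading", c(covars5, "x", "risk", "x*risk"), d)
  ss <- simpleSlopes(f, "x", "risk", levels = c(0, 1))
  # level 0 slope is the focal coefficient exactly
  expect_equal(ss$slope[1], unname(f$coef[["x"]]))
  # stratified refit oracle: slope within each genotype stratum
  for (g in c(0, 1)) {
    sub <- d[d$risk == g, ]
    fs <- fitOls("reading", c(covars5, "x"), sub)
    expect_lt(abs(ss$slope[g + 1] - fs$coef[["x"]]),
              3 * sqrt(ss$se[g + 1]^2 + fs$se[["x"]]^2))
  }
  # zero product coefficient -> identical slopes at all levels
  set.seed(2)
  d0 <- data.frame(x = rnorm(40), g = rbinom(40, 1, 0.5))
  d0$y <- 0.5 * d0$x + 0.3 * d0$g   # noiseless, no interaction
  f0 <- fitOls("y", c("x", "g", "x*g"), d0)
  ss0 <- simpleSlopes(f0, "x", "g", levels = c(0, 1, 2))
  expect_equal(ss0$slope, rep(0.5, 3), tolerance = 1e-10)
  expect_error(simpleSlopes(f, "x", "gender"), "product")
})

test_that("correlation-matrix regression equals direct OLS", {
  set.seed(8)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(0.5, -0.2, 0) + rnorm(n)
  d <- data.frame(X, y = drop(y))
  zd <- zscoreColumns(d, c("a", "b", "c", "y"))
  R <- cor(zd[c("a", "b", "c")])
  r <- drop(cor(zd[c("a", "b", "c")], zd$y))
  fc <- fitFromCorrelations(R, r, n)
  fo <- fitOls("y", c("a", "b", "c"), zd)
  expect_equal(unname(fc$beta), unname(fo$coef[c("a", "b", "c")]),
               tolerance = 1e-10)
  expect_equal(fc$r.squared, fo$r.squared, tolerance = 1e-10)
  # identity R -> beta = r; zero r -> zero fit
  expect_equal(unname(fitFromCorrelations(diag(3), r, n)$beta), unname(r))
  z <- fitFromCorrelations(R, rep(0, 3), n)
  expect_equal(unname(z$beta), rep(0, 3))
  expect_equal(z$r.squared, 0)
  expect_error(fitFromCorrelations(matrix(c(1, 2, 2, 1), 2), c(0, 0), 50),
               "positive definite")
})

test_that("interaction detection is calibrated under the null", {
  # no-interaction truth: the product-term test rejects at ~alpha
  set.seed(5150)
  rej <- vapply(1:200, function(i) {
    n <- 150
    g <- rbinom(n, 1, 0.3)
    x <- rnorm(n)
    y <- 0.2 * x + 0.1 * g + rnorm(n)
    f <- fitOls("y", c("x", "g", "x*g"), data.frame(x = x, g = g, y = y))
    f$p[["x*g"]] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
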