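test_that("noiseless weak diathesis-stress data is inverted exactly", {
  d <- sim_analysis_frame(41, simulationDesign(residualSd = 1e-10))
  tr <- attr(d, "truth")
  f <- fitReparam(d, "reading", "x", d$risk, covars5, model = "d")
  expect_equal(unname(f$estimates[["B0"]]), tr$B0, tolerance = 1e-8)
  expect_equal(unname(f$estimates[["B1"]]), tr$B1, tolerance = 1e-8)
  expect_equal(unname(f$estimates[["B3"]]), tr$B3, tolerance = 1e-8)
  expect_equal(f$C, tr$crossover_value)
  expect_equal(unname(f$estimates[["B5"]]), tr$B5, tolerance = 1e-8)
  expect_equal(f$r.squared, 1, tolerance = 1e-8)
})

test_that("model b equals the unconstrained OLS interaction fit", {
  # re-parameterization identity on random datasets
  for (i in 1:20) {
    set.seed(i)
    n <- 80
    g <- rbinom(n, 1, 0.3)
    if (min(table(g)) == 0) next
    x <- rnorm(n)
    cv <- rnorm(n)
    y <- rnorm(n) + 0.3 * x * g + 0.2 * cv
    d <- data.frame(y = y, x = x, g = g, cv = cv)
    f <- fitReparam(d, "y", "x", d$g, "cv", model = "b")
    ref <- lm(y ~ x * g + cv, data = d)
    expect_equal(f$sse, sum(resid(ref)^2), tolerance = 1e-8)
    # mapping identities against the OLS coefficients
    gam <- coef(ref)
    expect_equal(unname(f$estimates[["B1"]]), unname(gam["x"]),
                 tolerance = 1e-10)
    expect_equal(unname(f$estimates[["B3"]]),
                 unname(gam["x"] + gam["x:g"]), tolerance = 1e-10)
    expect_equal(f$C, unname(-gam["g"] / gam["x:g"]), tolerance = 1e-10)
  }
})

test_that("constrained fits respect their constraints and nesting", {
  d <- sim_analysis_frame(42)
  fits <- lapply(c(a = "a", b = "b", c = "c", d = "d", e = "e", f = "f"),
                 function(m) fitReparam(d, "reading", "x", d$risk,
                                        covars5, model = m))
  # B1 exactly zero in the strong models; C fixed at the extremes
  for (m in c("a", "c", "e"))
    expect_identical(unname(fits[[m]]$estimates[["B1"]]), 0)
  expect_equal(fits$c$C, max(d$x))
  expect_equal(fits$d$C, max(d$x))
  expect_equal(fits$e$C, min(d$x))
  expect_false(fits$b$C_free == FALSE)
  # nesting inequalities on R^2
  r2 <- vapply(fits, `[[`, 1, "r.squared")
  expect_lte(r2[["a"]], r2[["b"]] + 1e-10)
  expect_lte(r2[["c"]], min(r2[["a"]], r2[["d"]]) + 1e-10)
  expect_lte(r2[["e"]], min(r2[["a"]], r2[["f"]]) + 1e-10)
  expect_lte(r2[["d"]], r2[["b"]] + 1e-10)
  expect_lte(r2[["f"]], r2[["b"]] + 1e-10)
  # df convention: weak fixed-crossover model reports F(7, n-8)
  expect_equal(fits$d$fstat$df1, 7)
  expect_equal(fits$d$fstat$df2, 745 - 8)
  # optional nls polish confirms the closed-form optimum
  fb <- fitReparam(d, "reading", "x", d$risk, covars5, model = "b",
                   polish = TRUE)
  expect_equal(fb$sse, fits$b$sse, tolerance = 1e-8)
})

test_that("nested F-tests reduce to known identities", {
  d <- sim_analysis_frame(43)
  fb <- fitReparam(d, "reading", "x", d$risk, covars5, model = "b")
  # restricted = full -> F = 0, p = 1
  self <- nestedFTest(fb, fb)
  expect_equal(self$F, 0)
  expect_equal(self$p, 1)
  fd <- fitReparam(d, "reading", "x", d$risk, covars5, model = "d")
  nf <- nestedFTest(fd, fb)
  expect_equal(nf$df1, 1)
  expect_equal(nf$df2, 745 - 9)
  expect_gte(nf$F, 0)
  # single-constraint nesting: F(d vs b) relates to the crossover
  # release; F(a vs b) equals the squared t of B1 in the full linear
  # re-parameterization within numerical tolerance
  fa <- fitReparam(d, "reading", "x", d$risk, covars5, model = "a")
  ref <- lm(reading ~ x * risk + gender + age + pe_z + po_z + mi_z,
            data = d)
  t_b1 <- summary(ref)$coefficients["x", "t value"]
  nfa <- nestedFTest(fa, fb)
  expect_equal(nfa$F, t_b1^2, tolerance = 1e-6)
  # non-nested pair errors
  fc <- fitReparam(d, "reading", "x", d$risk, covars5, model = "c")
  ff <- fitReparam(d, "reading", "x", d$risk, covars5, model = "f")
  expect_error(nestedFTest(fc, ff), "not nested")
  expect_error(nestedFTest(fb, fd), "not nested")
})

test_that("information criteria follow the SSE/penalty arithmetic", {
  d <- sim_analysis_frame(44)
  fb <- fitReparam(d, "reading", "x", d$risk, covars5, model = "b")
  fd <- fitReparam(d, "reading", "x", d$risk, covars5, model = "d")
  n <- fb$n
  # recompute from SSE and k
  expect_equal(fb$aic, n * log(fb$sse / n) + 2 * fb$k)
  expect_equal(fb$bic, n * log(fb$sse / n) + fb$k * log(n))
  # counting the free crossover adds exactly 2 to AIC, log(n) to BIC
  ic <- informationCriteria(fb, countCrossover = TRUE)
  expect_equal(ic[["aic"]] - fb$aic, 2)
  expect_equal(ic[["bic"]] - fb$bic, log(n))
  # equal k: AIC ordering equals SSE ordering
  expect_equal(fb$k, fd$k)
  expect_equal(fb$aic < fd$aic, fb$sse < fd$sse)
})

test_that("confidence interval for the crossover is calibrated", {
  # model-b truth with an interior crossover; CI coverage ~95%
  des <- simulationDesign(trueModel = "b")
  hits <- vapply(1:80, function(i) {
    d <- sim_analysis_frame(7000 + i, des)
    tr <- attr(d, "truth")
    f <- fitReparam(d, "reading", "x", d$risk, covars5, model = "b")
    f$C_ci[1] <= tr$crossover_value && tr$crossover_value <= f$C_ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.85)  # 3-SE band around 0.95 at n = 80
})

test_that("selectModel rejects misfits and respects parsimony", {
  # strong vantage truth at large n: model e wins
  des_e <- simulationDesign(trueModel = "e", n = 5000,
                            params = list(B3 = 0.25))
  d <- sim_analysis_frame(901, des_e)
  cm <- selectModel(d, "reading", "x", d$risk, covars5)
  expect_equal(cm$selected, "e")
  # comparison table invariants
  expect_true(all(cm$table$r.squared[cm$table$ok] <=
                    cm$table$r.squared[cm$table$model == "b"] + 1e-10))
  expect_true(all(cm$table$dR2[!is.na(cm$table$dR2)] >= -1e-10))
  # markdown rendering carries exactly six model columns
  md <- formatComparisonMarkdown(cm)
  expect_equal(length(strsplit(md[1], "\\|")[[1]]), 7)
})
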