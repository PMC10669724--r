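test_that("JN boundaries match a fine grid search of |theta|/SE", {
  # grid oracle on simulated fits
  set.seed(2718)
  grid_roots <- function(bz, bxz, vzz, vzp, vpp, tcrit) {
    xs <- seq(-6, 6, by = 1e-4)
    ratio <- abs(bz + bxz * xs) /
      sqrt(vzz + 2 * xs * vzp + xs^2 * vpp)
    sig <- ratio > tcrit
    xs[which(diff(sig) != 0)]
  }
  n_checked <- 0
  for (i in 1:50) {
    n <- 150
    g <- rbinom(n, 1, 0.4)
    x <- rnorm(n)
    y <- 0.1 * x - 0.25 * g + runif(1, 0.1, 0.5) * x * g + rnorm(n)
    f <- fitOls("y", c("x", "g", "x*g"), data.frame(x = x, g = g, y = y))
    jn <- jnBoundaries(f, "x", "g")
    gr <- grid_roots(f$coef[["g"]], f$coef[["x*g"]],
                     f$vcov["g", "g"], f$vcov["g", "x*g"],
                     f$vcov["x*g", "x*g"], jn$t_crit)
    ana <- c(jn$lower, jn$upper)
    ana <- ana[!is.na(ana)]
    ana <- ana[ana > -6 & ana < 6]
    expect_equal(length(ana), length(gr))
    if (length(ana)) {
      expect_lt(max(abs(sort(ana) - sort(gr))), 1e-3)
      n_checked <- n_checked + length(ana)
    }
  }
  expect_gt(n_checked, 10)
})

test_that("JN roots plugged back give the critical ratio; V = 0 collapses", {
  d <- sim_analysis_frame(62)
  f <- fitOls("reading", c(covars5, "x", "risk", "x*risk"), d)
  jn <- jnBoundaries(f, "x", "risk")
  for (r in c(jn$lower, jn$upper)) {
    if (is.na(r)) next
    th <- f$coef[["risk"]] + f$coef[["x*risk"]] * r
    se <- sqrt(f$vcov["risk", "risk"] +
                 2 * r * f$vcov["risk", "x*risk"] +
                 r^2 * f$vcov["x*risk", "x*risk"])
    expect_equal(abs(th) / se, jn$t_crit, tolerance = 1e-6)
  }
  # zero-variance limit: theta(X) = -1 + 2X vanishes only at X = 0.5
  core <- jnBoundariesCore(-1, 2, 0, 0, 0, df = Inf)
  expect_equal(core$lower, 0.5, tolerance = 1e-12)
  expect_true(is.na(core$upper) || core$upper == 0.5)
  none <- jnBoundariesCore(0, 0, 1, 0, 1, df = 30)
  expect_true(none$no_moderation)
})

test_that("crossover point is the coefficient ratio, scale invariant", {
  expect_equal(crossoverPoint(-0.05, bxz = 0.09), 0.5556,
               tolerance = 1e-4)
  expect_equal(crossoverPoint(0, bxz = 0.2), 0)
  expect_equal(crossoverPoint(-0.1, bxz = 0.18),
               crossoverPoint(-0.05, bxz = 0.09))
  expect_error(crossoverPoint(0.3, bxz = 1e-12), "undefined")
  # fit interface agrees with the ratio of its own coefficients
  d <- sim_analysis_frame(63)
  f <- fitOls("reading", c(covars5, "x", "risk", "x*risk"), d)
  expect_equal(crossoverPoint(f, moderator = "risk", focal = "x"),
               -f$coef[["risk"]] / f$coef[["x*risk"]])
})

test_that("PoI equals the squared-distance ratio and its quadrature oracle", {
  # midpoint symmetry
  expect_equal(poiIndex(0, c(-2, 2))$poi, 0.5)
  # published trio: C = 0.49, range (-4.31, 1.85) -> 0.0743 -> 0.07
  p <- poiIndex(0.49, c(-4.31, 1.85))
  expect_equal(round(p$poi, 4), 0.0743)
  expect_equal(round(p$poi, 2), 0.07)
  # quadrature oracle: integrate |line1 - line2| on each side
  set.seed(10)
  for (i in 1:20) {
    s1 <- rnorm(1); s2 <- s1 + runif(1, 0.2, 1)  # positive interaction
    xc <- runif(1, -1, 1); lo <- -3; hi <- 2
    gap <- function(x) abs((s2 - s1) * (x - xc))
    b <- integrate(gap, xc, hi)$value
    w <- integrate(gap, lo, xc)$value
    expect_equal(poiIndex(xc, c(lo, hi))$poi, b / (b + w),
                 tolerance = 1e-8)
  }
  # mirror property and orientation flip
  expect_equal(poiIndex(0.7, c(-2, 2))$poi +
                 poiIndex(-2 + 2 - 0.7, c(-2, 2))$poi, 1)
  expect_equal(poiIndex(0.7, c(-2, 2), interactionSign = -1)$poi,
               1 - poiIndex(0.7, c(-2, 2))$poi)
  # out-of-range crossover clamps with a warning
  expect_warning(pc <- poiIndex(5, c(-2, 2)), "clamped")
  expect_equal(pc$poi, 0)
  expect_error(poiIndex(0, c(1, 1)), "degenerate")
})

test_that("PA index: empirical share, analytic tail, and their agreement", {
  expect_equal(paIndex(0, x = c(1, 2, 3))$pa, 1)
  # analytic-normal at the published crossover 0.49 -> 0.3121 -> 0.31
  pa <- paIndex(0.49, mode = "normal")
  expect_equal(round(pa$pa, 4), 0.3121)
  expect_equal(round(pa$pa, 2), 0.31)
  # Monte-Carlo convergence to the analytic value
  set.seed(66)
  z <- rnorm(1e6)
  emp <- paIndex(0.49, x = z)$pa
  p <- pa$pa
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / 1e6))
  # orientation flip
  expect_equal(paIndex(0.49, mode = "normal", interactionSign = -1)$pa,
               pnorm(0.49))
})

test_that("nonlinearity probe flags true curvature and passes linear data", {
  # noiseless linear outcome: quadratic coefficients vanish
  set.seed(17)
  n <- 300
  g <- rbinom(n, 1, 0.3); x <- rnorm(n)
  d <- data.frame(x = x, g = g, y = 0.3 * x + 0.2 * g + 0.1 * x * g)
  nl <- nonlinearityProbe("y", "x", "g", data = d)
  expect_lt(abs(nl$fit$coef[[".X2"]]), 1e-8)
  expect_lt(abs(nl$fit$coef[[".ZX2"]]), 1e-8)

  # true quadratic environment effect is detected at n = 745
  hits <- vapply(1:20, function(i) {
    set.seed(100 + i)
    n <- 745
    g <- rbinom(n, 1, 0.2); x <- rnorm(n)
    y <- 0.2 * x + 0.15 * x^2 + rnorm(n)
    nl <- nonlinearityProbe("y", "x", "g", data = data.frame(x, g, y))
    nl$p_x2 < 0.001
  }, logical(1))
  expect_gt(mean(hits), 0.5)

  # null calibration: linear truth rejects the quadratics at ~alpha
  set.seed(2020)
  rej <- vapply(1:150, function(i) {
    n <- 200
    g <- rbinom(n, 1, 0.3); x <- rnorm(n)
    y <- 0.2 * x + 0.1 * g + 0.15 * x * g + rnorm(n)
    nl <- nonlinearityProbe("y", "x", "g", data = data.frame(x, g, y))
    nl$p_x2 < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("Holm step-down matches the sequential Bonferroni rules", {
  h <- holmCorrection(c(0.005, 0.5, 0.9), alpha = 0.05)
  expect_equal(h$critical[1], 0.05 / 3, tolerance = 1e-12)
  expect_equal(round(h$critical[1], 2), 0.02)
  expect_equal(h$reject, c(TRUE, FALSE, FALSE))
  # all p = 1 -> nothing; single test -> critical value alpha
  expect_false(any(holmCorrection(rep(1, 4))$reject))
  expect_equal(holmCorrection(0.04)$critical, 0.05)
  expect_true(holmCorrection(0.04)$reject)
  # step-down stopping: later small p cannot rescue after a failure
  h2 <- holmCorrection(c(0.04, 0.0005, 0.03), alpha = 0.05)
  expect_equal(h2$reject, c(TRUE, FALSE, FALSE))

  # Holm rejections: superset of Bonferroni, subset of uncorrected
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))^2
    h <- holmCorrection(p, alpha = 0.05)
    bonf <- p[h$index] < 0.05 / length(p)
    unc <- p[h$index] < 0.05
    expect_true(all(h$reject[bonf]))
    expect_true(all(unc[h$reject]))
    expect_true(all(diff(h$critical) >= 0))
    # rejections form a prefix of the sorted list
    expect_true(all(diff(as.integer(h$reject)) <= 0))
  }
})
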