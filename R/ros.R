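#' Johnson-Neyman significance boundaries on the environment
#'
#' The genotype-group difference in expected outcome at environment
#' value X is \eqn{\theta(X) = b_Z + b_{XZ} X} (moderator main effect
#' plus product coefficient).  The Johnson-Neyman boundaries are the
#' real roots of
#' \deqn{(b_{XZ}^2 - t^2 V_{pp})X^2 + 2(b_Z b_{XZ} - t^2 V_{zp})X +
#'       (b_Z^2 - t^2 V_{zz}) = 0}
#' with \eqn{t = t_{1-\alpha/2}} on the fit's residual df: the X values
#' where \eqn{|\theta(X)|/SE(\theta(X))} equals the critical t.
#'
#' @param fit an [fitOls()] result containing the moderator main
#'   effect and the focal-by-moderator product.
#' @param focal focal (environment) term name.
#' @param moderator moderator (genotype) term name.
#' @param alpha two-sided significance level (default 0.05).
#' @return a `RosResult`: `lower`/`upper` boundaries (NA when absent),
#'   `n_roots`, `t_crit`, `theta` (function of X), significance
#'   classification over the observed range and over mean +/- 2 SD,
#'   and the evaluation ranges themselves.
#' @export
jnBoundaries <- function(fit, focal, moderator, alpha = 0.05) {
  stopifnot(inherits(fit, "OlsFit"))
  if (!moderator %in% fit$terms)
    stop("moderator term '", moderator, "' not in fit")
  prod_term <- .find_product_term(fit, focal, moderator)
  bz <- fit$coef[[moderator]]; bxz <- fit$coef[[prod_term]]
  V <- fit$vcov
  core <- jnBoundariesCore(bz, bxz,
                           vzz = V[moderator, moderator],
                           vzp = V[moderator, prod_term],
                           vpp = V[prod_term, prod_term],
                           df = fit$df.residual, alpha = alpha)
  xobs <- fit$model[[focal]]
  obs_range <- range(xobs)
  m2sd_range <- mean(xobs) + c(-2, 2) * sd(xobs)
  sig_at <- function(x) {
    th <- bz + bxz * x
    se <- sqrt(V[moderator, moderator] + 2 * x * V[moderator, prod_term] +
                 x^2 * V[prod_term, prod_term])
    abs(th) / se > core$t_crit
  }
  classify <- function(rng) {
    lo_sig <- sig_at(rng[1]); hi_sig <- sig_at(rng[2])
    if (lo_sig && hi_sig) "both" else if (lo_sig) "low X only" else
      if (hi_sig) "high X only" else "neither"
  }
  out <- c(core,
           list(obs_range = obs_range, m2sd_range = m2sd_range,
                classification_obs = classify(obs_range),
                classification_m2sd = classify(m2sd_range),
                focal = focal, moderator = moderator,
                product = prod_term))
  class(out) <- "RosResult"
  out
}

#' Johnson-Neyman boundary computation from coefficients
#'
#' Coefficient-level core of [jnBoundaries()]; useful when only the
#' group-difference intercept/slope and their covariance are at hand.
#' With a zero covariance block the roots collapse to the crossover
#' point itself.
#'
#' @param bz moderator (group difference at X = 0) coefficient.
#' @param bxz product (difference-in-slopes) coefficient.
#' @param vzz,vzp,vpp covariance entries of `(bz, bxz)`.
#' @param df residual degrees of freedom (`Inf` for a normal critical
#'   value).
#' @param alpha two-sided level.
#' @return list with `lower`, `upper`, `n_roots`, `t_crit`,
#'   `no_moderation` flag.
#' @export
jnBoundariesCore <- function(bz, bxz, vzz, vzp, vpp, df, alpha = 0.05) {
  t_crit <- if (is.infinite(df)) qnorm(1 - alpha / 2) else
    qt(1 - alpha / 2, df)
  if (abs(bz) < 1e-12 && abs(bxz) < 1e-12)
    return(list(lower = NA_real_, upper = NA_real_, n_roots = 0L,
                t_crit = t_crit, no_moderation = TRUE))
  t2 <- t_crit^2
  A <- bxz^2 - t2 * vpp
  B <- 2 * (bz * bxz - t2 * vzp)
  C <- bz^2 - t2 * vzz
  eps <- 1e-14 * max(abs(c(A, B, C, 1)))
  if (abs(A) <= eps) {
    roots <- if (abs(B) > eps) -C / B else numeric(0)
  } else {
    disc <- B^2 - 4 * A * C
    roots <- if (disc < 0) numeric(0) else if (disc == 0) -B / (2 * A) else
      sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }
  list(lower = if (length(roots) >= 1) roots[1] else NA_real_,
       upper = if (length(roots) == 2) roots[2] else NA_real_,
       n_roots = length(roots), t_crit = t_crit, no_moderation = FALSE)
}

#' @export
print.RosResult <- function(x, digits = 4, ...) {
  cat("Johnson-Neyman regions of significance\n")
  cat(sprintf("  boundaries: %s, %s (t_crit = %.3f)\n",
              ifelse(is.na(x$lower), "none", format(round(x$lower, digits))),
              ifelse(is.na(x$upper), "none", format(round(x$upper, digits))),
              x$t_crit))
  cat(sprintf("  observed X range [%.3f, %.3f]: difference significant at %s\n",
              x$obs_range[1], x$obs_range[2], x$classification_obs))
  cat(sprintf("  M +/- 2 SD range [%.3f, %.3f]: %s\n",
              x$m2sd_range[1], x$m2sd_range[2], x$classification_m2sd))
  invisible(x)
}

#' Crossover point of the two genotype-group regression lines
#'
#' \eqn{X_c = -b_Z / b_{XZ}}: the environment value where the group
#' lines intersect.
#'
#' @param fit an [fitOls()] result, or a numeric `bz` coefficient.
#' @param moderator,focal term names (fit interface).
#' @param bxz difference-in-slopes coefficient (numeric interface).
#' @param tol slope-difference magnitude below which the crossover is
#'   undefined.
#' @return the crossover point (scalar).
#' @export
crossoverPoint <- function(fit, moderator = NULL, focal = NULL,
                           bxz = NULL, tol = 1e-10) {
  if (is.numeric(fit)) {
    bz <- fit
  } else {
    stopifnot(inherits(fit, "OlsFit"))
    prod_term <- .find_product_term(fit, focal, moderator)
    bz <- fit$coef[[moderator]]
    bxz <- fit$coef[[prod_term]]
  }
  if (abs(bxz) < tol)
    stop("interaction coefficient ~0; crossover point undefined")
  -bz / bxz
}

#' Proportion-of-interaction (PoI) index
#'
#' With two straight regression lines crossing at `xc`, the area
#' between them on either side of the crossover grows as the squared
#' distance to the range end, so
#' \deqn{PoI = (hi - X_c)^2 / ((hi - X_c)^2 + (X_c - lo)^2)}
#' for a positive interaction (good side = high X); the orientation
#' flips for a negative interaction.  PoI near 0.5 supports
#' differential susceptibility; near 0, diathesis-stress.
#'
#' @param xc crossover point; values outside the range are clamped to
#'   it with a warning.
#' @param range evaluation range `c(lo, hi)` of the environment --
#'   conventionally the observed min/max or mean +/- 2 SD.
#' @param interactionSign sign of the difference-in-slopes coefficient
#'   (+1: risk group gains more at high X).
#' @return a `PoiPa` list: `xc`, good area `b`, bad area `w`, `poi`,
#'   `range`, `clamped`.
#' @export
poiIndex <- function(xc, range, interactionSign = 1) {
  lo <- range[1]; hi <- range[2]
  if (!(lo < hi)) stop("degenerate range: need lo < hi")
  clamped <- FALSE
  if (xc < lo || xc > hi) {
    warning("crossover point ", format(xc), " outside range; clamped")
    xc <- min(max(xc, lo), hi)
    clamped <- TRUE
  }
  good <- (hi - xc)^2
  bad <- (xc - lo)^2
  if (interactionSign < 0) { tmp <- good; good <- bad; bad <- tmp }
  structure(list(xc = xc, b = good, w = bad,
                 poi = good / (good + bad), range = c(lo, hi),
                 clamped = clamped, interactionSign = sign(interactionSign)),
            class = "PoiPa")
}

#' Proportion-affected (PA) index
#'
#' Share of participants whose environment value lies on the "good"
#' side of the crossover point -- empirically over observed values, or
#' analytically as the standard-normal tail beyond `xc` when X is
#' standardized.  PA >= 0.16 is the conventional requirement for
#' differential susceptibility.
#'
#' @param xc crossover point.
#' @param x observed environment values (empirical mode).
#' @param mode `"empirical"` or `"normal"`.
#' @param interactionSign +1 if the good side is above `xc`.
#' @return a `PoiPa` list with the `pa` element set.
#' @export
paIndex <- function(xc, x = NULL, mode = c("empirical", "normal"),
                    interactionSign = 1) {
  mode <- match.arg(mode)
  if (mode == "empirical") {
    if (is.null(x) || !length(x)) stop("empirical PA needs observed x values")
    x <- x[!is.na(x)]
    pa <- if (interactionSign >= 0) mean(x > xc) else mean(x < xc)
  } else {
    pa <- if (interactionSign >= 0) pnorm(xc, lower.tail = FALSE) else
      pnorm(xc)
  }
  structure(list(xc = xc, pa = pa, mode = mode,
                 interactionSign = sign(interactionSign)),
            class = "PoiPa")
}

#' @export
print.PoiPa <- function(x, ...) {
  if (!is.null(x$poi))
    cat(sprintf("PoI = %.4f (crossover %.4f in [%.3f, %.3f]%s)\n",
                x$poi, x$xc, x$range[1], x$range[2],
                if (isTRUE(x$clamped)) ", clamped" else ""))
  if (!is.null(x$pa))
    cat(sprintf("PA = %.4f (%s, crossover %.4f)\n", x$pa, x$mode, x$xc))
  invisible(x)
}

#' Quadratic nonlinearity probe of an interaction
#'
#' Refits the interaction model augmented with \eqn{X^2} and
#' \eqn{Z X^2} terms.  A spurious differential-susceptibility signal
#' can arise when the environment-outcome relation is curvilinear in
#' one genotype group only; the probe reports whether the quadratic
#' terms predict the outcome and whether the focal product term stays
#' significant once they are controlled.
#'
#' @param y outcome column name.
#' @param focal environment column name (X).
#' @param moderator genotype column name (Z).
#' @param covariates additional term names.
#' @param data data frame.
#' @param alpha significance level for the summary flags.
#' @return a `NonlinearityCheck`: p-values for `X2`, `ZX2` and the
#'   `XZ` product in the augmented model, plus the augmented fit.
#' @export
nonlinearityProbe <- function(y, focal, moderator, covariates = character(),
                              data, alpha = 0.05) {
  data <- as.data.frame(data)
  data[[".X2"]] <- as.numeric(data[[focal]])^2
  data[[".ZX2"]] <- as.numeric(data[[moderator]]) * data[[".X2"]]
  prod <- paste0(focal, "*", moderator)
  terms <- c(covariates, focal, moderator, prod, ".X2", ".ZX2")
  fit <- fitOls(y, terms, data)
  out <- list(p_x2 = fit$p[[".X2"]], p_zx2 = fit$p[[".ZX2"]],
              p_xz = fit$p[[prod]],
              quadratic_significant = fit$p[[".X2"]] < alpha ||
                fit$p[[".ZX2"]] < alpha,
              interaction_robust = fit$p[[prod]] < alpha,
              alpha = alpha, fit = fit)
  class(out) <- "NonlinearityCheck"
  out
}

#' @export
print.NonlinearityCheck <- function(x, ...) {
  cat(sprintf("Nonlinearity probe: p(X^2) = %.4f, p(ZX^2) = %.4f\n",
              x$p_x2, x$p_zx2))
  cat(sprintf("  XZ product in augmented model: p = %.4f (%ssignificant at %.2f)\n",
              x$p_xz, if (x$interaction_robust) "" else "not ", x$alpha))
  invisible(x)
}

#' Sequential Bonferroni (Holm) step-down correction
#'
#' Sorts the m p-values ascending and compares the i-th smallest to
#' \eqn{\alpha/(m - i + 1)}; testing stops at the first failure, so the
#' rejections always form a prefix of the sorted list.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return a `HolmResult` data frame: original index, sorted p,
#'   per-rank critical value, rejection flag.
#' @export
holmCorrection <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  crit <- alpha / (m - seq_len(m) + 1)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (is.na(p[ord[i]]) || p[ord[i]] >= crit[i]) break
    reject[i] <- TRUE
  }
  out <- data.frame(index = ord, p = p[ord], critical = crit,
                    reject = reject)
  attr(out, "alpha") <- alpha
  class(out) <- c("HolmResult", "data.frame")
  out
}
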