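#' @importFrom stats nls nls.control predict
NULL

# Constraint sets of the six interaction models relative to the weak
# differential susceptibility model (b), which is the full model:
#   strong variants fix the non-risk slope B1 = 0; diathesis-stress
#   fixes the crossover C at the environment maximum, vantage
#   sensitivity at the minimum.
.reparam_models <- list(
  a = list(label = "strong differential susceptibility",
           B1zero = TRUE,  crossover = "free"),
  b = list(label = "weak differential susceptibility",
           B1zero = FALSE, crossover = "free"),
  c = list(label = "strong diathesis-stress",
           B1zero = TRUE,  crossover = "max"),
  d = list(label = "weak diathesis-stress",
           B1zero = FALSE, crossover = "max"),
  e = list(label = "strong vantage sensitivity",
           B1zero = TRUE,  crossover = "min"),
  f = list(label = "weak vantage sensitivity",
           B1zero = FALSE, crossover = "min")
)

.constraint_set <- function(model) {
  m <- .reparam_models[[model]]
  out <- character(0)
  if (m$B1zero) out <- c(out, "B1=0")
  if (m$crossover != "free") out <- c(out, paste0("C=", m$crossover))
  out
}

#' Fit the re-parameterized crossover regression
#'
#' Fits the two-group mean function
#' \deqn{E[Y] = B_0 + B_1 (X - C) \;[non-risk]\quad /\quad
#'       B_0 + B_3 (X - C) \;[risk] \;+\; \textstyle\sum_j B_j X_j}
#' under the constraint set of one of the six strong/weak interaction
#' models.  With the crossover C fixed (models c-f) the model is
#' linear.  With C free (models a, b) the fit uses the exact linear
#' re-parameterization -- e.g. for model b, OLS of
#' `Y ~ X + G + X:G + covariates` followed by the mapping
#' \eqn{B_1 = \gamma_X}, \eqn{B_3 = \gamma_X + \gamma_{XG}},
#' \eqn{C = -\gamma_G/\gamma_{XG}},
#' \eqn{B_0 = \gamma_0 + B_1 C} -- whose least-squares optimum is the
#' global optimum of the nonlinear problem, so no iterative search is
#' required.  `polish = TRUE` additionally runs [stats::nls()] from
#' the closed-form solution as a verification pass.
#'
#' The standard error of a free C comes from the delta method on the
#' ratio \eqn{-\gamma_G/\gamma_{XG}} with the OLS coefficient
#' covariance; its 95% CI is \eqn{C \pm t_{0.975}\,SE}.
#'
#' Degrees-of-freedom convention: the overall F and the information
#' criteria count only the linear mean coefficients (k = 8 for the
#' weak models with five covariates; the crossover is not counted),
#' while nested comparisons via [nestedFTest()] count every released
#' constraint including a freed crossover.  Set
#' `countCrossover = TRUE` to include a free C in the information
#' criteria penalty instead.
#'
#' @param data data frame (typically a standardized cohort view).
#' @param y outcome column name.
#' @param x environment column name (standardized).
#' @param group risk-group indicator column (0 = non-risk D1,
#'   1 = risk/plastic D2) or a numeric/logical vector.
#' @param covariates covariate column names (coefficients B4...).
#' @param model one of `"a"`..`"f"`.
#' @param crossover optional numeric override of the fixed crossover
#'   (defaults: observed `max(x)` for c/d, `min(x)` for e/f).
#' @param countCrossover count a free crossover in the AIC/BIC penalty?
#' @param polish verify the free-C solution with an [stats::nls()]
#'   pass started from the closed form.
#' @param slopeTol unidentified-crossover threshold on the absolute
#'   slope difference |B3 - B1| for free-C models.
#' @return a `ReparamFit`: `estimates`, `se`, `t`, `p` (named B0, B1,
#'   B3 and one B per covariate), `C`, `C_se`, `C_ci`, `C_free`,
#'   `sse`, `sst`, `r.squared`, `fstat`, `aic`, `bic`, `k` (penalty
#'   count), `kNested` (free parameters incl. C, for nested tests),
#'   `n`, `model`, `constraints`.
#' @export
fitReparam <- function(data, y, x, group, covariates = character(),
                       model = c("b", "a", "c", "d", "e", "f"),
                       crossover = NULL, countCrossover = FALSE,
                       polish = FALSE, slopeTol = 1e-10) {
  model <- match.arg(model)
  spec <- .reparam_models[[model]]
  data <- as.data.frame(data)
  g <- if (is.character(group) && length(group) == 1L) data[[group]] else group
  g <- as.numeric(g)
  yv <- as.numeric(data[[y]])
  xv <- as.numeric(data[[x]])
  covm <- if (length(covariates))
    as.matrix(as.data.frame(lapply(data[covariates], as.numeric)))
  else matrix(numeric(0), nrow(data), 0)
  ok <- !is.na(yv) & !is.na(xv) & !is.na(g) &
    (if (ncol(covm)) complete.cases(covm) else TRUE)
  yv <- yv[ok]; xv <- xv[ok]; g <- g[ok]
  covm <- covm[ok, , drop = FALSE]
  n <- length(yv)
  if (!all(g %in% c(0, 1))) stop("group must be coded 0/1")
  if (min(table(g)) == 0) stop("both genotype groups must be non-empty")

  cov_names <- if (ncol(covm)) paste0("B", 3 + seq_len(ncol(covm)) )
    else character(0)

  if (spec$crossover == "free") {
    # exact linear re-parameterization
    if (spec$B1zero) {
      X <- cbind(`(Intercept)` = 1, G = g, XG = xv * g, covm)
    } else {
      X <- cbind(`(Intercept)` = 1, X = xv, G = g, XG = xv * g, covm)
    }
    ls <- .ls_fit(X, yv)
    gamma <- ls$coef; V <- ls$vcov
    slope_diff <- gamma[["XG"]]
    if (abs(slope_diff) < slopeTol)
      stop("slope difference ~0; crossover unidentified for model ", model)
    C <- -gamma[["G"]] / gamma[["XG"]]
    B1 <- if (spec$B1zero) 0 else gamma[["X"]]
    B3 <- B1 + gamma[["XG"]]
    B0 <- gamma[["(Intercept)"]] + B1 * C
    # delta-method SEs through the mapping
    gn <- colnames(X)
    grad_of <- function(d) { v <- stats::setNames(numeric(length(gn)), gn); v[names(d)] <- d; v }
    gG <- gamma[["G"]]; gXG <- gamma[["XG"]]
    grC <- grad_of(c(G = -1 / gXG, XG = gG / gXG^2))
    se_from <- function(gr) sqrt(max(drop(t(gr) %*% V %*% gr), 0))
    C_se <- se_from(grC)
    if (spec$B1zero) {
      B1_se <- NA_real_
      B3_se <- sqrt(V["XG", "XG"])
      grB0 <- grad_of(c(`(Intercept)` = 1))
    } else {
      B1_se <- sqrt(V["X", "X"])
      B3_se <- sqrt(V["X", "X"] + 2 * V["X", "XG"] + V["XG", "XG"])
      # B0 = g0 - gX * gG / gXG
      grB0 <- grad_of(c(`(Intercept)` = 1, X = -gG / gXG,
                        G = -gamma[["X"]] / gXG,
                        XG = gamma[["X"]] * gG / gXG^2))
    }
    B0_se <- se_from(grB0)
    cov_est <- if (ncol(covm)) gamma[colnames(covm)] else numeric(0)
    cov_se <- if (ncol(covm)) sqrt(diag(V)[colnames(covm)]) else numeric(0)
    sse <- ls$sse
    k_lin <- ncol(X)            # linear coefficients incl. the C carrier
    k <- k_lin - 1L             # reported parameters: C not counted
    kNested <- k_lin            # free parameters incl. C, for nested F
    df_C <- n - k_lin
    C_ci <- C + c(-1, 1) * qt(0.975, df_C) * C_se
    if (polish) {
      pol <- .polish_nls(yv, xv, g, covm, spec$B1zero,
                         start = list(B0 = B0, B1 = B1, B3 = B3, C = C,
                                      covs = cov_est))
      if (!is.null(pol) && pol$sse < sse * (1 - 1e-12)) {
        # nls found a better optimum (should not happen; kept as guard)
        B0 <- pol$B0; B1 <- pol$B1; B3 <- pol$B3; C <- pol$C
        cov_est <- pol$covs; sse <- pol$sse
      }
    }
  } else {
    C <- if (!is.null(crossover)) as.numeric(crossover) else
      if (spec$crossover == "max") max(xv) else min(xv)
    xc <- xv - C
    if (spec$B1zero) {
      X <- cbind(`(Intercept)` = 1, XC2 = xc * g, covm)
    } else {
      X <- cbind(`(Intercept)` = 1, XC1 = xc * (1 - g), XC2 = xc * g, covm)
    }
    ls <- .ls_fit(X, yv)
    gamma <- ls$coef; V <- ls$vcov
    B0 <- gamma[["(Intercept)"]]; B0_se <- sqrt(V[1, 1])
    B1 <- if (spec$B1zero) 0 else gamma[["XC1"]]
    B1_se <- if (spec$B1zero) NA_real_ else sqrt(V["XC1", "XC1"])
    B3 <- gamma[["XC2"]]; B3_se <- sqrt(V["XC2", "XC2"])
    cov_est <- if (ncol(covm)) gamma[colnames(covm)] else numeric(0)
    cov_se <- if (ncol(covm)) sqrt(diag(V)[colnames(covm)]) else numeric(0)
    sse <- ls$sse
    k <- ncol(X)
    kNested <- k
    C_se <- NA_real_; C_ci <- c(NA_real_, NA_real_)
  }

  sst <- sum((yv - mean(yv))^2)
  r2 <- 1 - sse / sst
  df1 <- k - 1L; df2 <- n - k
  fval <- (r2 / df1) / ((1 - r2) / df2)
  kIC <- k + as.integer(countCrossover && spec$crossover == "free")
  est <- c(B0 = B0, B1 = B1, B3 = B3, cov_est)
  ses <- c(B0 = B0_se, B1 = B1_se, B3 = B3_se, cov_se)
  names(est) <- names(ses) <- c("B0", "B1", "B3", cov_names)
  df_t <- n - kNested
  tv <- est / ses
  pv <- 2 * pt(-abs(tv), df = df_t)
  if (spec$B1zero) { tv[["B1"]] <- NA; pv[["B1"]] <- NA }
  out <- list(model = model, label = spec$label,
              constraints = .constraint_set(model),
              estimates = est, se = ses, t = tv, p = pv,
              covariates = covariates,
              C = C, C_se = C_se, C_ci = C_ci,
              C_free = spec$crossover == "free",
              crossover_rule = spec$crossover,
              sse = sse, sst = sst, r.squared = r2,
              fstat = list(value = fval, df1 = df1, df2 = df2,
                           p = pf(fval, df1, df2, lower.tail = FALSE)),
              aic = n * log(sse / n) + 2 * kIC,
              bic = n * log(sse / n) + kIC * log(n),
              k = k, kIC = kIC, kNested = kNested, n = n)
  class(out) <- "ReparamFit"
  out
}

# plain least squares returning coefficients, covariance and SSE
.ls_fit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design in crossover fit")
  b <- qr.coef(qrX, y)
  res <- y - drop(X %*% b)
  sse <- sum(res^2)
  df <- length(y) - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  list(coef = b, vcov = (sse / df) * XtXinv, sse = sse, df = df)
}

# optional nls verification of a free-crossover fit
.polish_nls <- function(y, x, g, covm, B1zero, start) {
  dd <- data.frame(y = y, x = x, g = g)
  covpart <- ""
  st <- list(B0 = start$B0, B3 = start$B3, C = start$C)
  if (!B1zero) st$B1 <- start$B1
  if (ncol(covm)) {
    for (j in seq_len(ncol(covm))) {
      nm <- paste0("cv", j)
      dd[[nm]] <- covm[, j]
      covpart <- paste0(covpart, " + a", j, "*", nm)
      st[[paste0("a", j)]] <- unname(start$covs[j])
    }
  }
  slope <- if (B1zero) "(g*B3)" else "((1-g)*B1 + g*B3)"
  form <- stats::as.formula(paste0("y ~ B0 + ", slope, "*(x - C)", covpart))
  fit <- tryCatch(
    stats::nls(form, data = dd, start = st,
               control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  list(B0 = cf[["B0"]], B1 = if (B1zero) 0 else cf[["B1"]],
       B3 = cf[["B3"]], C = cf[["C"]],
       covs = if (ncol(covm)) cf[paste0("a", seq_len(ncol(covm)))] else numeric(0),
       sse = sum(stats::resid(fit)^2))
}

#' @export
print.ReparamFit <- function(x, digits = 3, ...) {
  cat(sprintf("Re-parameterized crossover fit, model %s (%s)\n",
              x$model, x$label))
  if (length(x$constraints))
    cat("  constraints:", paste(x$constraints, collapse = ", "), "\n")
  tab <- data.frame(estimate = x$estimates, se = x$se, t = x$t, p = x$p,
                    sig = .stars(x$p))
  print(round(tab[1:4], digits))
  if (x$C_free)
    cat(sprintf("  C = %.3f (SE %.3f), 95%% CI [%.3f, %.3f]\n",
                x$C, x$C_se, x$C_ci[1], x$C_ci[2]))
  else
    cat(sprintf("  C fixed at %.3f (%s of X)\n", x$C, x$crossover_rule))
  cat(sprintf("  R^2 = %.3f, F(%d, %d) = %.2f, AIC = %.3f, BIC = %.3f\n",
              x$r.squared, x$fstat$df1, x$fstat$df2, x$fstat$value,
              x$aic, x$bic))
  invisible(x)
}

#' Nested F-test between two crossover-model fits
#'
#' \deqn{F = \frac{(SSE_r - SSE_f)/\Delta df}{SSE_f/df_f}}
#' where \eqn{\Delta df} counts every constraint the full model
#' releases (a fixed crossover counts as one) and \eqn{df_f = n -
#' k_{free}} uses the full model's free-parameter count including a
#' free crossover.
#'
#' @param restricted,full `ReparamFit` objects on the same data; the
#'   restricted model's constraint set must be a superset of the
#'   full's.
#' @return list with `F`, `df1`, `df2`, `p`, `dR2`.
#' @export
nestedFTest <- function(restricted, full) {
  stopifnot(inherits(restricted, "ReparamFit"), inherits(full, "ReparamFit"))
  if (restricted$n != full$n || abs(restricted$sst - full$sst) > 1e-6 * full$sst)
    stop("fits are not on the same data")
  if (setequal(restricted$constraints, full$constraints) &&
      restricted$kNested == full$kNested)
    return(list(F = 0, df1 = 0L, df2 = full$n - full$kNested, p = 1,
                dR2 = 0))
  if (!all(full$constraints %in% restricted$constraints) ||
      restricted$kNested >= full$kNested)
    stop("models are not nested: '", restricted$model,
         "' is not a restriction of '", full$model, "'")
  df1 <- full$kNested - restricted$kNested
  df2 <- full$n - full$kNested
  dSSE <- max(restricted$sse - full$sse, 0)
  Fv <- (dSSE / df1) / (full$sse / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE),
       dR2 = full$r.squared - restricted$r.squared)
}

#' Information criteria of a crossover fit
#'
#' \eqn{AIC = n\ln(SSE/n) + 2k}, \eqn{BIC = n\ln(SSE/n) + k\ln n},
#' with k the number of counted mean parameters (see [fitReparam()]
#' for the crossover-counting convention).
#'
#' @param fit a `ReparamFit`.
#' @param countCrossover include a free crossover in k?
#' @return named numeric vector `c(aic, bic)`.
#' @export
informationCriteria <- function(fit, countCrossover = FALSE) {
  stopifnot(inherits(fit, "ReparamFit"))
  k <- fit$k + as.integer(countCrossover && fit$C_free)
  base <- fit$n * log(fit$sse / fit$n)
  c(aic = base + 2 * k, bic = base + k * log(fit$n))
}

#' Fit and compare the six interaction models
#'
#' Fits models a-f, tests each alternative against the weak
#' differential susceptibility model (b) with [nestedFTest()] at level
#' `alpha`, rejects any alternative fitting significantly worse, and
#' among the surviving models accepts the most constrained one
#' (ties broken by lower BIC, then lower AIC).  If every alternative
#' is rejected, model b is accepted.
#'
#' @inheritParams fitReparam
#' @param alpha level of the nested F-tests.
#' @param ... passed to [fitReparam()].
#' @return a `ComparisonTable`: `fits` (list a-f), `table` (per-model
#'   R2, F, F-vs-b, AIC, BIC, verdict), `selected` model id,
#'   `rationale` string.
#' @export
selectModel <- function(data, y, x, group, covariates = character(),
                        alpha = 0.05, ...) {
  ids <- names(.reparam_models)
  fits <- list(); errors <- list()
  for (m in ids) {
    fits[[m]] <- tryCatch(
      fitReparam(data, y, x, group, covariates, model = m, ...),
      error = function(e) e)
  }
  full <- fits[["b"]]
  if (inherits(full, "error"))
    stop("reference model b failed: ", conditionMessage(full))
  rows <- list(); verdicts <- character(0)
  for (m in ids) {
    f <- fits[[m]]
    if (inherits(f, "error")) {
      rows[[m]] <- data.frame(model = m, ok = FALSE, r.squared = NA,
                              F_vs_b = NA, df1 = NA, df2 = NA, p_vs_b = NA,
                              dR2 = NA, aic = NA, bic = NA,
                              n_constraints = NA, rejected = NA)
      verdicts <- c(verdicts, paste0("model ", m, ": estimation error (",
                                     conditionMessage(f), ")"))
      next
    }
    if (m == "b") {
      rows[[m]] <- data.frame(model = m, ok = TRUE,
                              r.squared = f$r.squared, F_vs_b = NA,
                              df1 = NA, df2 = NA, p_vs_b = NA, dR2 = NA,
                              aic = f$aic, bic = f$bic,
                              n_constraints = 0L, rejected = FALSE)
      next
    }
    nf <- nestedFTest(f, full)
    rejected <- nf$p < alpha
    rows[[m]] <- data.frame(model = m, ok = TRUE, r.squared = f$r.squared,
                            F_vs_b = nf$F, df1 = nf$df1, df2 = nf$df2,
                            p_vs_b = nf$p, dR2 = nf$dR2,
                            aic = f$aic, bic = f$bic,
                            n_constraints = length(f$constraints),
                            rejected = rejected)
    verdicts <- c(verdicts, sprintf(
      "model %s vs b: F(%d, %d) = %.3f, p = %.4g -> %s", m, nf$df1,
      nf$df2, nf$F, nf$p, if (rejected) "rejected" else "retained"))
  }
  tab <- do.call(rbind, rows)
  cand <- tab[!is.na(tab$rejected) & !tab$rejected & tab$ok, ]
  if (nrow(cand) == 1L && cand$model == "b") {
    selected <- "b"
    verdicts <- c(verdicts,
                  "all alternatives rejected -> model b accepted")
  } else {
    cand <- cand[order(-cand$n_constraints, cand$bic, cand$aic), ]
    selected <- cand$model[1]
    verdicts <- c(verdicts, sprintf(
      "most constrained surviving model: %s (%s)", selected,
      .reparam_models[[selected]]$label))
  }
  out <- list(fits = fits, table = tab, selected = selected,
              alpha = alpha, rationale = verdicts)
  class(out) <- "ComparisonTable"
  out
}

#' @export
print.ComparisonTable <- function(x, digits = 4, ...) {
  cat("Six-model crossover comparison (alpha =", x$alpha, ")\n")
  print(round_df(x$table, digits))
  cat("selected:", x$selected, "-",
      .reparam_models[[x$selected]]$label, "\n")
  invisible(x)
}

round_df <- function(df, digits) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]))
    df[[j]] <- round(df[[j]], digits)
  df
}

#' Render a six-model comparison as a markdown grid
#'
#' One column per model a-f; rows B0..B8, C with its CI, R2, overall
#' F, F vs b, AIC and BIC, with significance stars.
#'
#' @param comparison a [selectModel()] result.
#' @param digits decimals for estimates.
#' @return character vector of markdown lines.
#' @export
formatComparisonMarkdown <- function(comparison, digits = 2) {
  ids <- names(.reparam_models)
  okfits <- Filter(function(f) inherits(f, "ReparamFit"), comparison$fits)
  if (!length(okfits)) stop("no successful fits to render")
  pnames <- names(okfits[[1]]$estimates)
  cell <- function(f, p) {
    if (inherits(f, "error")) return("--")
    e <- f$estimates[[p]]; s <- f$se[[p]]
    if (p == "B1" && "B1=0" %in% f$constraints)
      return("0.00 (--)")
    sprintf("%.*f (%.*f)%s", digits, e, digits, s, .stars(f$p[[p]]))
  }
  lines <- c(paste(c("Parameter", ids), collapse = " | "),
             paste(rep("---", 7), collapse = " | "))
  for (p in pnames)
    lines <- c(lines, paste(c(p, vapply(comparison$fits, cell, "", p = p)),
                            collapse = " | "))
  crow <- vapply(comparison$fits, function(f) {
    if (inherits(f, "error")) "--" else if (f$C_free)
      sprintf("%.*f (%.*f)", digits, f$C, digits, f$C_se) else
        sprintf("%.*f (fixed)", digits, f$C)
  }, "")
  cirow <- vapply(comparison$fits, function(f) {
    if (inherits(f, "error") || !f$C_free) "--" else
      sprintf("[%.*f, %.*f]", digits, f$C_ci[1], digits, f$C_ci[2])
  }, "")
  stat <- function(fun) vapply(comparison$fits, function(f)
    if (inherits(f, "error")) "--" else fun(f), "")
  lines <- c(lines,
    paste(c("C", crow), collapse = " | "),
    paste(c("95% CI of C", cirow), collapse = " | "),
    paste(c("R^2", stat(function(f) sprintf("%.3f", f$r.squared))),
          collapse = " | "),
    paste(c("F (df)", stat(function(f)
      sprintf("%.2f (%d, %d)%s", f$fstat$value, f$fstat$df1, f$fstat$df2,
              .stars(f$fstat$p)))), collapse = " | "),
    paste(c("F vs b (df)", vapply(ids, function(m) {
      r <- comparison$table[comparison$table$model == m, ]
      if (m == "b" || !isTRUE(r$ok)) "--" else
        sprintf("%.2f (%d, %d)%s", r$F_vs_b, r$df1, r$df2,
                .stars(r$p_vs_b))
    }, "")), collapse = " | "),
    paste(c("AIC", stat(function(f) sprintf("%.3f", f$aic))),
          collapse = " | "),
    paste(c("BIC", stat(function(f) sprintf("%.3f", f$bic))),
          collapse = " | "))
  c(lines, "",
    paste0("Selected model: ", comparison$selected, " (",
           .reparam_models[[comparison$selected]]$label, "). ",
           "* p < 0.05, ** p < 0.01, *** p < 0.001."))
}

#' Two-line interaction plot of a crossover fit
#'
#' Draws the fitted environment-outcome lines of the two genotype
#' groups (covariates at zero) with the crossover marked.
#'
#' @param fit a `ReparamFit`.
#' @param xlim environment range to draw (default the fitted C +/- 3).
#' @param labels group labels.
#' @param file optional SVG output path.
#' @return invisibly, the plotted line parameters.
#' @export
plotInteraction <- function(fit, xlim = NULL, labels = c("non-risk (D1)",
                                                         "risk/plastic (D2)"),
                            file = NULL) {
  stopifnot(inherits(fit, "ReparamFit"))
  if (is.null(xlim)) xlim <- fit$C + c(-3, 3)
  if (!is.null(file)) grDevices::svg(file, width = 6, height = 4.5)
  xx <- seq(xlim[1], xlim[2], length.out = 50)
  b0 <- fit$estimates[["B0"]]
  y1 <- b0 + fit$estimates[["B1"]] * (xx - fit$C)
  y2 <- b0 + fit$estimates[["B3"]] * (xx - fit$C)
  graphics::plot(range(xx), range(c(y1, y2)), type = "n",
                 xlab = "environment (standardized)",
                 ylab = "predicted outcome",
                 main = paste("Model", fit$model, "-", fit$label))
  graphics::lines(xx, y1, lty = 1, lwd = 2)
  graphics::lines(xx, y2, lty = 2, lwd = 2, col = "purple")
  graphics::abline(v = fit$C, col = "grey60", lty = 3)
  graphics::legend("topleft", legend = labels, lty = 1:2,
                   col = c("black", "purple"), lwd = 2, bty = "n")
  if (!is.null(file)) grDevices::dev.off()
  invisible(list(x = xx, y1 = y1, y2 = y2, C = fit$C))
}
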