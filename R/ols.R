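#' @importFrom stats lm model.matrix pf vcov coef
NULL

# Expand a term language of variable names and `a*b` / `a:b` products
# into a numeric design data frame (one column per term).
.build_terms <- function(terms, data) {
  cols <- list()
  for (tm in terms) {
    parts <- strsplit(tm, "[*:]")[[1]]
    parts <- trimws(parts)
    absent <- setdiff(parts, names(data))
    if (length(absent))
      stop("term '", tm, "' references missing column(s): ",
           paste(absent, collapse = ", "))
    v <- Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
    cols[[tm]] <- v
  }
  as.data.frame(cols, check.names = FALSE, optional = TRUE)
}

#' Ordinary least squares fit with standardized coefficients
#'
#' Fits `y` on an intercept plus the listed terms (plain column names
#' or `a*b` products, formed from the columns as given -- products of
#' already-standardized components are *not* re-standardized).
#' Standardized coefficients are \eqn{\beta_j = b_j\,SD(x_j)/SD(y)}
#' using each term column's own SD, so interaction terms remain
#' comparable with the main effects.
#'
#' @param y outcome column name.
#' @param terms character vector of predictor terms; `a*b` (or `a:b`)
#'   denotes the elementwise product.
#' @param data data frame containing all columns.
#' @param na.action rows with missing values are dropped listwise.
#' @return an `OlsFit`: coefficients (`coef`), `se`, `t`, `p`,
#'   standardized `beta`, covariance matrix `vcov`, `r.squared`,
#'   `sse`, `sst`, `fstat` (list value/df1/df2/p), `sigma`,
#'   `df.residual`, `n`, and the model frame used (`model`).
#' @export
fitOls <- function(y, terms, data, na.action = stats::na.omit) {
  stopifnot(y %in% names(data))
  if (anyDuplicated(terms))
    stop("duplicate term(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  X <- .build_terms(terms, data)
  d <- cbind(stats::setNames(data.frame(as.numeric(data[[y]])), y), X)
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k <- length(terms)
  if (n <= k + 1) stop("need n > number of terms (incl. intercept)")
  yv <- d[[1]]
  Xm <- cbind(`(Intercept)` = 1, as.matrix(d[, -1, drop = FALSE]))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dep <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
    stop("collinear design; dependent term(s): ",
         paste(dep, collapse = ", "))
  }
  b <- qr.coef(qrX, yv)
  fitted <- drop(Xm %*% b)
  res <- yv - fitted
  sse <- sum(res^2)
  sst <- sum((yv - mean(yv))^2)
  df2 <- n - ncol(Xm)
  sigma2 <- sse / df2
  XtXinv <- chol2inv(chol(crossprod(Xm)))
  dimnames(XtXinv) <- list(colnames(Xm), colnames(Xm))
  V <- sigma2 * XtXinv
  se <- sqrt(diag(V))
  tval <- b / se
  pval <- 2 * pt(-abs(tval), df = df2)
  r2 <- 1 - sse / sst
  df1 <- ncol(Xm) - 1
  fval <- if (df1 > 0) (r2 / df1) / ((1 - r2) / df2) else NA_real_
  sdy <- sd(yv)
  beta <- b
  beta["(Intercept)"] <- NA_real_
  for (tm in terms) beta[tm] <- b[tm] * sd(d[[tm]]) / sdy
  out <- list(terms = colnames(Xm), coef = b, se = se, t = tval, p = pval,
              beta = beta, vcov = V,
              r.squared = r2, sse = sse, sst = sst,
              fstat = list(value = fval, df1 = df1, df2 = df2,
                           p = if (df1 > 0) pf(fval, df1, df2,
                                               lower.tail = FALSE) else NA),
              sigma = sqrt(sigma2), df.residual = df2, n = n,
              residuals = res, fitted = fitted,
              yname = y, model = d)
  class(out) <- "OlsFit"
  out
}

#' @export
print.OlsFit <- function(x, digits = 4, ...) {
  cat("OLS fit:", x$yname, "~", paste(x$terms[-1], collapse = " + "),
      " (n =", x$n, ")\n")
  tab <- data.frame(b = x$coef, beta = x$beta, se = x$se, t = x$t,
                    p = x$p, sig = .stars(x$p))
  print(round(tab[1:5], digits))
  cat(sprintf("R^2 = %.4f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r.squared, x$fstat$df1, x$fstat$df2, x$fstat$value,
              x$fstat$p))
  invisible(x)
}

#' Hierarchical (block-entry) regression
#'
#' Fits an ordered sequence of nested term blocks (each extending the
#' previous) and reports per-block \eqn{\Delta R^2} and its F-test
#' \eqn{\Delta F = (\Delta R^2/\Delta k)\,/\,((1 - R^2_k)/(n - k - 1))}
#' evaluated against the current block's residual variance.
#'
#' @param y outcome column name.
#' @param blocks list of character vectors; block `i` must contain all
#'   terms of block `i-1`.
#' @param data data frame.
#' @return a `HierarchicalResult`: `fits` (list of [fitOls()] objects),
#'   `steps` (data frame of R2, dR2, dF, dfs, p per block).
#' @export
hierarchicalBlocks <- function(y, blocks, data) {
  if (!length(blocks)) stop("need at least one block")
  for (i in seq_along(blocks)[-1])
    if (!all(blocks[[i - 1]] %in% blocks[[i]]))
      stop("blocks must be nested: block ", i,
           " does not contain all terms of block ", i - 1)
  # listwise-complete rows over the final block so every step sees the
  # same n (standard hierarchical-regression practice)
  allterms <- blocks[[length(blocks)]]
  d <- cbind(data[y], .build_terms(allterms, data))
  d <- d[complete.cases(d), , drop = FALSE]
  fits <- lapply(blocks, function(tms) fitOls(y, tms, d))
  steps <- data.frame(block = seq_along(blocks),
                      k = vapply(blocks, length, 1L),
                      r.squared = vapply(fits, `[[`, 1, "r.squared"),
                      dR2 = NA_real_, dF = NA_real_,
                      df1 = NA_real_, df2 = NA_real_, p = NA_real_)
  n <- fits[[1]]$n
  for (i in seq_along(fits)) {
    r2_prev <- if (i == 1) 0 else steps$r.squared[i - 1]
    dk <- steps$k[i] - (if (i == 1) 0 else steps$k[i - 1])
    if (dk == 0) {
      steps$dR2[i] <- 0
      next
    }
    r2 <- steps$r.squared[i]
    df2 <- n - steps$k[i] - 1
    dF <- ((r2 - r2_prev) / dk) / ((1 - r2) / df2)
    steps$dR2[i] <- r2 - r2_prev
    steps$dF[i] <- dF
    steps$df1[i] <- dk; steps$df2[i] <- df2
    steps$p[i] <- pf(dF, dk, df2, lower.tail = FALSE)
  }
  structure(list(blocks = blocks, fits = fits, steps = steps, n = n,
                 yname = y),
            class = "HierarchicalResult")
}

#' @export
print.HierarchicalResult <- function(x, digits = 4, ...) {
  cat("Hierarchical regression of", x$yname, "(n =", x$n, ")\n")
  print(round(x$steps[-1], digits))
  invisible(x)
}

# locate the product term of two components in a fit, trying both
# orders and both separators
.find_product_term <- function(fit, a, b) {
  cand <- c(paste0(a, "*", b), paste0(b, "*", a),
            paste0(a, ":", b), paste0(b, ":", a))
  hit <- cand[cand %in% fit$terms]
  if (!length(hit))
    stop("fit contains no product term of '", a, "' and '", b, "'")
  hit[1]
}

#' Simple slopes of a focal predictor at chosen moderator levels
#'
#' For a fit containing the focal term, the moderator and their
#' product, the conditional slope at moderator level m is
#' \eqn{b_f + b_p m} with variance
#' \eqn{V_{ff} + 2 m V_{fp} + m^2 V_{pp}}.
#'
#' @param fit an [fitOls()] result.
#' @param focal focal predictor term name.
#' @param moderator moderator term name.
#' @param levels numeric moderator values at which to evaluate.
#' @param labels optional level labels.
#' @return data frame of class `SimpleSlopes`: level, slope, se, t, p.
#' @export
simpleSlopes <- function(fit, focal, moderator, levels,
                         labels = as.character(levels)) {
  stopifnot(inherits(fit, "OlsFit"))
  if (!focal %in% fit$terms) stop("focal term '", focal, "' not in fit")
  prod_term <- .find_product_term(fit, focal, moderator)
  bf <- fit$coef[[focal]]; bp <- fit$coef[[prod_term]]
  Vff <- fit$vcov[focal, focal]
  Vfp <- fit$vcov[focal, prod_term]
  Vpp <- fit$vcov[prod_term, prod_term]
  slope <- bf + bp * levels
  v <- Vff + 2 * levels * Vfp + levels^2 * Vpp
  se <- sqrt(pmax(v, 0))
  tval <- slope / se
  out <- data.frame(label = labels, level = levels, slope = slope,
                    se = se, t = tval,
                    p = 2 * pt(-abs(tval), df = fit$df.residual))
  class(out) <- c("SimpleSlopes", "data.frame")
  out
}

#' Standardized regression from a correlation matrix
#'
#' Solves the normal equations on the correlation scale:
#' \eqn{\beta = R^{-1} r}, \eqn{R^2 = r^\top \beta},
#' \eqn{F = (R^2/k) / ((1 - R^2)/(n - k - 1))}.
#'
#' @param R predictor correlation matrix (positive definite).
#' @param r vector of predictor-outcome correlations.
#' @param n sample size.
#' @return list with `beta`, `r.squared`, `fstat` (value/df1/df2/p).
#' @export
fitFromCorrelations <- function(R, r, n) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || length(r) != nrow(R))
    stop("dimension mismatch between R and r")
  ch <- tryCatch(chol(R), error = function(e)
    stop("predictor correlation matrix is not positive definite"))
  beta <- drop(chol2inv(ch) %*% r)
  names(beta) <- rownames(R)
  r2 <- drop(crossprod(r, beta))
  k <- length(r)
  df2 <- n - k - 1
  fval <- (r2 / k) / ((1 - r2) / df2)
  list(beta = beta, r.squared = r2,
       fstat = list(value = fval, df1 = k, df2 = df2,
                    p = pf(fval, k, df2, lower.tail = FALSE)))
}
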