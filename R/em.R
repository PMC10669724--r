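#' Multivariate-normal EM imputation of missing values
#'
#' Fits a multivariate normal to the selected numeric columns by
#' expectation-maximization under ignorable missingness, then replaces
#' each missing cell by its conditional mean given the row's observed
#' entries at the converged parameters.
#'
#' The E-step computes, per missingness pattern, the conditional mean
#' \eqn{\mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(x_o - \mu_o)} and the
#' conditional covariance \eqn{\Sigma_{mm} -
#' \Sigma_{mo}\Sigma_{oo}^{-1}\Sigma_{om}} of the missing block, and
#' accumulates expected first and second moments; the M-step updates
#' the mean and (ML) covariance from those moments.  The observed-data
#' log-likelihood is recorded every iteration and is monotone
#' non-decreasing; convergence is declared when its relative change
#' falls below `tol`.  A near-singular covariance is ridged by
#' `ridge * trace/dim` on the diagonal with a warning.
#'
#' @param table data frame (e.g. a [cohortTable()]).
#' @param variables numeric columns to model and impute.
#' @param tol relative log-likelihood convergence threshold.
#' @param maxIter iteration cap; exceeding it is an error (the trace is
#'   attached to the condition as the `trace` field).
#' @param ridge diagonal regularization factor for near-singular
#'   covariance updates.
#' @return a list: `data` (the table with missing cells filled),
#'   `mu`, `sigma` (ML estimates), `loglik` (per-iteration trace),
#'   `iterations`, `converged`, `n_imputed`.
#' @export
emImpute <- function(table, variables, tol = 1e-6, maxIter = 500,
                     ridge = 1e-8) {
  stopifnot(all(variables %in% names(table)))
  x <- as.matrix(as.data.frame(table)[variables])
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  miss <- is.na(x)
  if (any(colSums(miss) == n))
    stop("variable(s) entirely missing: ",
         paste(variables[colSums(miss) == n], collapse = ", "))
  if (!any(miss)) {
    mu <- colMeans(x)
    sigma <- cov(x) * (n - 1) / n
    return(list(data = table, mu = mu, sigma = sigma,
                loglik = .dmvnorm_logsum(x, mu, sigma),
                iterations = 1L, converged = TRUE, n_imputed = 0L))
  }

  # starting values: available-case means, pairwise covariance
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- suppressWarnings(cov(x, use = "pairwise.complete.obs"))
  sigma[!is.finite(sigma)] <- 0
  if (any(!is.finite(diag(sigma))) || any(diag(sigma) <= 0))
    diag(sigma) <- pmax(diag(sigma), apply(x, 2, var, na.rm = TRUE), 1e-6)
  sigma <- .em_regularize(sigma, ridge, quiet = TRUE)

  pattern <- apply(miss, 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), pattern)
  ll_trace <- numeric(0)
  converged <- FALSE
  warned_ridge <- FALSE

  for (iter in seq_len(maxIter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (rows in groups) {
      m <- miss[rows[1], ]
      o <- !m
      xo <- x[rows, o, drop = FALSE]
      So <- sigma[o, o, drop = FALSE]
      ll <- ll + .dmvnorm_logsum(xo, mu[o], So)
      if (!any(m)) {
        T1 <- T1 + colSums(x[rows, , drop = FALSE])
        T2 <- T2 + crossprod(x[rows, , drop = FALSE])
        next
      }
      B <- sigma[m, o, drop = FALSE] %*% solve(So)
      cm <- matrix(mu[m], nrow = length(rows), ncol = sum(m), byrow = TRUE) +
        sweep(xo, 2, mu[o]) %*% t(B)
      Cmm <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
      xfill <- matrix(0, length(rows), p)
      xfill[, o] <- xo
      xfill[, m] <- cm
      T1 <- T1 + colSums(xfill)
      T2e <- crossprod(xfill)
      T2e[m, m] <- T2e[m, m] + length(rows) * Cmm
      T2 <- T2 + T2e
    }
    ll_trace <- c(ll_trace, ll)
    mu_new <- T1 / n
    sigma_new <- T2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    reg <- .em_regularize(sigma_new, ridge, quiet = warned_ridge)
    if (!identical(reg, sigma_new) && !warned_ridge) warned_ridge <- TRUE
    mu <- mu_new; sigma <- reg
    if (iter >= 2) {
      rel <- abs(ll_trace[iter] - ll_trace[iter - 1]) /
        (abs(ll_trace[iter - 1]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    cond <- simpleError(paste0("EM did not converge within ", maxIter,
                               " iterations"))
    cond$trace <- ll_trace
    stop(cond)
  }

  filled <- x
  for (rows in groups) {
    m <- miss[rows[1], ]
    if (!any(m)) next
    o <- !m
    B <- sigma[m, o, drop = FALSE] %*% solve(sigma[o, o, drop = FALSE])
    cm <- matrix(mu[m], nrow = length(rows), ncol = sum(m), byrow = TRUE) +
      sweep(x[rows, o, drop = FALSE], 2, mu[o]) %*% t(B)
    filled[rows, m] <- cm
  }
  out <- table
  for (j in seq_len(p)) out[[variables[j]]] <- filled[, j]
  list(data = out, mu = mu, sigma = sigma, loglik = ll_trace,
       iterations = length(ll_trace), converged = TRUE,
       n_imputed = sum(miss))
}

# sum of log N(x; mu, S) over rows of x (x has no NAs)
.dmvnorm_logsum <- function(x, mu, S) {
  q <- ncol(x)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    S <- S + diag(1e-8 * mean(diag(S)) + 1e-12, q)
    ch <- chol(S)
  }
  z <- backsolve(ch, t(sweep(x, 2, mu)), transpose = TRUE)
  -0.5 * nrow(x) * (q * log(2 * pi) + 2 * sum(log(diag(ch)))) -
    0.5 * sum(z * z)
}

.em_regularize <- function(sigma, ridge, quiet = FALSE) {
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (ok && rcond(sigma) > 1e-12) return(sigma)
  if (!quiet)
    warning("near-singular covariance in EM update; ridge applied")
  sigma + diag(ridge * sum(diag(sigma)) / ncol(sigma) + 1e-12, ncol(sigma))
}
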