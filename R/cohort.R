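#' @importFrom stats complete.cases cor cov pnorm pt qt sd var
NULL

# Canonical column roles of a cohort table and their admissible ranges.
# Ordinal codes outside these ranges are coerced to NA at read time.
.cohort_roles <- list(
  child_id            = NULL,
  gender              = c(1, 2),
  age                 = c(0, 100),
  parental_education  = c(1, 6),
  parental_occupation = c(1, 10),
  monthly_income      = c(1, 5),
  home_supervision    = NULL,
  reading             = NULL
)
.hs_item_range <- c(1, 5)

#' Construct a cohort table
#'
#' A `CohortTable` is a validated `data.frame` of per-child phenotypes,
#' covariates and genotype calls: the single tabular currency of the
#' analysis pipeline.  Columns follow canonical role names (`gender`,
#' `age`, `parental_education`, `parental_occupation`, `monthly_income`,
#' `home_supervision` and/or `hs1`..`hs5`, `reading`) plus one string
#' column per SNP.  Out-of-range ordinal codes are converted to `NA`
#' and counted; missingness is always explicit, never zero-filled.
#'
#' @param data a `data.frame` with canonical column names.
#' @param snps character vector naming the genotype-call columns.
#' @param validate coerce out-of-range codes to `NA` (with a warning)?
#' @return a `CohortTable` (a `data.frame` subclass) with attributes
#'   `snps` and `n_coerced` (count of out-of-range cells blanked).
#' @export
cohortTable <- function(data, snps = character(), validate = TRUE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2L)
    stop("a cohort table needs at least 2 rows, got ", nrow(data))
  missing_snps <- setdiff(snps, names(data))
  if (length(missing_snps))
    stop("genotype columns absent from data: ",
         paste(missing_snps, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  n_coerced <- 0L
  if (validate) {
    for (role in names(.cohort_roles)) {
      rng <- .cohort_roles[[role]]
      if (is.null(rng) || !role %in% names(data)) next
      v <- suppressWarnings(as.numeric(data[[role]]))
      bad <- !is.na(v) & (v < rng[1] | v > rng[2])
      # non-numeric strings in numeric roles also count as coerced
      bad_parse <- is.na(v) & !is.na(data[[role]]) & data[[role]] != "" &
        !(is.character(data[[role]]) & trimws(as.character(data[[role]])) %in% c("NA", "na"))
      v[bad] <- NA_real_
      n_coerced <- n_coerced + sum(bad) + sum(bad_parse)
      data[[role]] <- v
    }
    for (it in grep("^hs[1-5]$", names(data), value = TRUE)) {
      v <- suppressWarnings(as.numeric(data[[it]]))
      bad <- !is.na(v) & (v < .hs_item_range[1] | v > .hs_item_range[2])
      v[bad] <- NA_real_
      n_coerced <- n_coerced + sum(bad)
      data[[it]] <- v
    }
    for (s in snps) {
      v <- as.character(data[[s]])
      v[!is.na(v) & (v == "" | v %in% c("NA", "na"))] <- NA_character_
      data[[s]] <- v
    }
    if (n_coerced > 0L)
      warning(n_coerced, " out-of-range value(s) converted to missing")
  }
  items <- grep("^hs[1-5]$", names(data), value = TRUE)
  if (!"home_supervision" %in% names(data) && length(items) == 5L)
    data$home_supervision <- rowSums(data[items])
  structure(data,
            snps = snps, n_coerced = n_coerced,
            class = c("CohortTable", "data.frame"))
}

#' @export
print.CohortTable <- function(x, ...) {
  cat("CohortTable:", nrow(x), "children,", ncol(x), "columns\n")
  snps <- attr(x, "snps")
  if (length(snps)) cat("  SNPs:", paste(snps, collapse = ", "), "\n")
  nc <- attr(x, "n_coerced")
  if (!is.null(nc) && nc > 0) cat("  out-of-range cells blanked:", nc, "\n")
  nm <- sum(is.na(as.matrix(x[vapply(x, is.numeric, TRUE)])))
  cat("  missing numeric cells:", nm, "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a cohort table from CSV/TSV
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param schema named character vector mapping canonical roles (see
#'   [cohortTable()]) to column names in the file.  Roles absent from
#'   the schema keep their canonical name if present in the file.
#' @param snps character vector of SNP column names (file names; mapped
#'   through `schema` if listed there).
#' @param sep field separator override.
#' @return a validated [cohortTable()].
#' @export
readCohort <- function(path, schema = NULL, snps = character(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    absent <- schema[!schema %in% names(raw)]
    if (length(absent))
      stop("schema maps role(s) ", paste(names(absent), collapse = ", "),
           " to column(s) missing from the file: ",
           paste(absent, collapse = ", "))
    idx <- match(schema, names(raw))
    names(raw)[idx] <- names(schema)
    snps <- ifelse(snps %in% schema, names(schema)[match(snps, schema)], snps)
  }
  needed <- c("gender", "age", "reading")
  lack <- setdiff(needed, names(raw))
  if (length(lack))
    stop("required column(s) missing: ", paste(lack, collapse = ", "))
  if (!"home_supervision" %in% names(raw) &&
      !all(paste0("hs", 1:5) %in% names(raw)))
    stop("required column(s) missing: home_supervision (or items hs1..hs5)")
  cohortTable(raw, snps = snps)
}

#' Write a cohort table (and optional truth sidecar) to CSV
#'
#' @param table a [cohortTable()].
#' @param path output CSV path.
#' @param truth optional list of generating parameters; written as a
#'   JSON sidecar `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(table, path, truth = attr(table, "truth")) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  if (!is.null(truth)) {
    truth <- truth[vapply(truth, length, 1L) <= 1L]  # drop per-row vectors
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Z-standardize selected columns
#'
#' Replaces each selected column by its Z score over non-missing
#' entries, using the sample standard deviation (denominator n-1).
#' Missing cells stay missing.  The means and SDs used are recorded so
#' the transformation is auditable and invertible.
#'
#' @param table a data frame or [cohortTable()].
#' @param variables character vector of numeric column names.
#' @return the table with class `StandardizedView` prepended and an
#'   attribute `standardization`: a data frame of variable, mean, sd.
#' @export
zscoreColumns <- function(table, variables) {
  stopifnot(all(variables %in% names(table)))
  std <- data.frame(variable = variables, mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(variables)) {
    v <- table[[variables[i]]]
    ok <- !is.na(v)
    if (sum(ok) < 2L)
      stop("variable '", variables[i], "' has fewer than 2 non-missing values")
    m <- mean(v[ok]); s <- sd(v[ok])
    if (!is.finite(s) || s == 0)
      stop("variable '", variables[i], "' has zero variance; cannot standardize")
    table[[variables[i]]] <- (v - m) / s
    std$mean[i] <- m; std$sd[i] <- s
  }
  prev <- attr(table, "standardization")
  if (!is.null(prev)) std <- rbind(prev[!prev$variable %in% std$variable, ], std)
  attr(table, "standardization") <- std
  if (!inherits(table, "StandardizedView"))
    class(table) <- c("StandardizedView", class(table))
  table
}

#' Cronbach's alpha internal-consistency reliability
#'
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2}
#' are item variances and \eqn{s_T^2} the variance of the item sum,
#' computed on listwise-complete rows with sample variances (n-1).
#'
#' @param items matrix or data frame of k >= 2 item scores.
#' @return the reliability coefficient (scalar).
#' @export
cronbachAlpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items")
  items <- items[complete.cases(items), , drop = FALSE]
  if (nrow(items) < 3L) stop("need at least 3 complete rows")
  k <- ncol(items)
  total_var <- var(rowSums(items))
  if (total_var <= 0) stop("total-score variance is zero; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / total_var)
}

#' Descriptive statistics and Pearson correlation report
#'
#' Pearson r for every variable pair with two-sided p-values from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 df, plus per-variable mean
#' and SD.  Pairs are formed on pairwise-complete observations by
#' default, or listwise-complete rows.
#'
#' @param table data frame with the variables.
#' @param variables character vector of numeric column names.
#' @param use `"pairwise"` (default) or `"listwise"`.
#' @return a `CorrelationReport`: list with `mean`, `sd`, `r`, `p`,
#'   `n` (matrix of pair sizes), `undefined` (logical matrix flagging
#'   constant-variable pairs).
#' @export
correlationReport <- function(table, variables,
                              use = c("pairwise", "listwise")) {
  use <- match.arg(use)
  stopifnot(all(variables %in% names(table)))
  x <- as.matrix(as.data.frame(table)[variables])
  storage.mode(x) <- "double"
  if (use == "listwise") x <- x[complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); nmat <- matrix(NA_real_, k, k)
  undef <- matrix(FALSE, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(nmat) <- dimnames(undef) <-
    list(variables, variables)
  diag(nmat) <- colSums(!is.na(x))
  diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j >= i) next
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n < 3L) { undef[i, j] <- undef[j, i] <- TRUE; next }
    si <- sd(x[ok, i]); sj <- sd(x[ok, j])
    if (si == 0 || sj == 0) {
      undef[i, j] <- undef[j, i] <- TRUE
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    rij <- cor(x[ok, i], x[ok, j])
    rij <- max(-1, min(1, rij))
    r[i, j] <- r[j, i] <- rij
    tij <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * pt(-abs(tij), df = n - 2)
  }
  out <- list(variables = variables,
              mean = apply(x, 2, mean, na.rm = TRUE),
              sd = apply(x, 2, sd, na.rm = TRUE),
              r = r, p = p, n = nmat, undefined = undef, use = use)
  class(out) <- "CorrelationReport"
  out
}

.stars <- function(p, cuts = c(0.001, 0.01, 0.05),
                   sym = c("***", "**", "*")) {
  out <- character(length(p))
  for (i in seq_along(p)) {
    out[i] <- if (is.na(p[i])) "" else if (p[i] < cuts[1]) sym[1] else
      if (p[i] < cuts[2]) sym[2] else if (p[i] < cuts[3]) sym[3] else ""
  }
  out
}

#' @export
print.CorrelationReport <- function(x, digits = 2, ...) {
  cat("Correlation report (", x$use, "-complete)\n\n", sep = "")
  cat(formatCorrelationMarkdown(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Render a correlation report as a markdown table
#'
#' Lower-triangular r matrix with significance stars
#' (* p < 0.05, ** p < 0.01) and an M (SD) column.
#'
#' @param report a [correlationReport()] result.
#' @param digits decimals for r.
#' @return character vector of markdown lines.
#' @export
formatCorrelationMarkdown <- function(report, digits = 2) {
  k <- length(report$variables)
  hdr <- c("Variable", "M (SD)", as.character(seq_len(k)))
  rows <- vapply(seq_len(k), function(i) {
    cells <- character(k)
    for (j in seq_len(k)) {
      cells[j] <- if (j > i) "" else if (j == i) "1.00" else {
        rij <- report$r[i, j]
        if (is.na(rij)) "--" else
          paste0(formatC(rij, digits = digits, format = "f"),
                 .stars(report$p[i, j], cuts = c(Inf, 0.01, 0.05),
                        sym = c("", "**", "*")))
      }
    }
    paste(c(paste0(i, ". ", report$variables[i]),
            sprintf("%.2f (%.2f)", report$mean[i], report$sd[i]), cells),
          collapse = " | ")
  }, character(1))
  c(paste(hdr, collapse = " | "),
    paste(rep("---", length(hdr)), collapse = " | "),
    rows,
    "", "Note: * p < 0.05, ** p < 0.01.")
}

#' Write a correlation report to CSV
#'
#' @param report a [correlationReport()] result.
#' @param path output CSV path (r matrix with M, SD columns).
#' @return `path`, invisibly.
#' @export
writeCorrelationCsv <- function(report, path) {
  df <- data.frame(variable = report$variables,
                   M = report$mean, SD = report$sd,
                   round(report$r, 6), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
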