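#' Pipeline configuration
#'
#' Collects every analysis choice of the end-to-end pipeline: the
#' input (a cohort file or a simulation design), genotype coding and
#' QC thresholds, and the analysis options (significance level, PoI
#' range convention, PA mode, risk-group coding, crossover counting).
#'
#' @param input path to a cohort CSV/TSV, or `NULL` to simulate.
#' @param design a [simulationDesign()] used when `input` is `NULL`.
#' @param schema column-role mapping passed to [readCohort()].
#' @param snps genotype column names (file input).
#' @param codingSchemes list of [codingScheme()] objects.
#' @param thresholds a [qcThresholds()].
#' @param alpha significance level used throughout.
#' @param poiRange PoI range convention: `"observed"` min/max (the
#'   default) or `"m2sd"` (mean +/- 2 SD).
#' @param paMode `"empirical"` or `"normal"` proportion-affected mode.
#' @param riskSnp,riskGenotype SNP and call defining the risk/plastic
#'   group for the confirmatory stage.
#' @param emImputation run EM imputation on numeric variables?
#' @param countCrossover passed to [fitReparam()].
#' @param seed RNG seed governing every stochastic stage.
#' @param outDir optional output directory for reports and tables.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(input = NULL, design = simulationDesign(),
                           schema = NULL, snps = NULL,
                           codingSchemes = defaultCodingSchemes(),
                           thresholds = qcThresholds(), alpha = 0.05,
                           poiRange = c("observed", "m2sd"),
                           paMode = c("empirical", "normal"),
                           riskSnp = "rs11629841", riskGenotype = "GT",
                           emImputation = TRUE, countCrossover = FALSE,
                           seed = 20231027, outDir = NULL) {
  poiRange <- match.arg(poiRange)
  paMode <- match.arg(paMode)
  structure(list(input = input, design = design, schema = schema,
                 snps = snps, codingSchemes = codingSchemes,
                 thresholds = thresholds, alpha = alpha,
                 poiRange = poiRange, paMode = paMode,
                 riskSnp = riskSnp, riskGenotype = riskGenotype,
                 emImputation = emImputation,
                 countCrossover = countCrossover,
                 seed = seed, outDir = outDir),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys match the arguments of
#' [pipelineConfig()]; `design` may be a list of
#' [simulationDesign()] arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `PipelineConfig`.
#' @export
loadPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[names(raw) %in% names(formals(pipelineConfig))]
  if (!is.null(args$design) && !inherits(args$design, "SimulationDesign")) {
    # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
    names(args$design)[names(args$design) %in% c("FALSE", "N", "no")] <- "n"
    args$design <- do.call(simulationDesign, args$design)
  }
  if (!is.null(args$thresholds) && !inherits(args$thresholds, "QcThresholds"))
    args$thresholds <- do.call(qcThresholds, args$thresholds)
  if (!is.null(args$schema)) args$schema <- unlist(args$schema)
  do.call(pipelineConfig, args)
}

.z <- function(v) {
  m <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero variance; cannot standardize")
  (v - m) / s
}

#' Run the full gene-environment analysis pipeline
#'
#' Executes, in order: input (read or simulate), genotype coding and
#' QC, EM imputation of missing numeric data, standardization,
#' descriptive correlations, hierarchical moderated regression
#' (covariates, then main effects, then interactions), RoS diagnostics
#' (Johnson-Neyman boundaries, crossover, PoI, PA, nonlinearity probe,
#' Holm correction of the interaction p-values), the six-model
#' crossover comparison and model selection.  Any stage error aborts
#' with the stage name; the completed stages are attached to the
#' condition as `partial`.
#'
#' @param config a [pipelineConfig()].
#' @return a `RunReport` list with one element per stage plus the
#'   selected model and an interpretation sentence.  If
#'   `config$outDir` is set, `report.json`, `report.md` and
#'   `tables/*.csv` are written there.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  report <- list(meta = list(
    package = "gxecross",
    version = as.character(utils::packageVersion("gxecross")),
    seed = config$seed,
    options = list(alpha = config$alpha, poiRange = config$poiRange,
                   paMode = config$paMode, riskSnp = config$riskSnp,
                   riskGenotype = config$riskGenotype,
                   emImputation = config$emImputation,
                   countCrossover = config$countCrossover,
                   input = if (is.null(config$input)) "simulated"
                           else config$input)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                 conditionMessage(e)))
      cond$partial <- report
      stop(cond)
    })
  }

  tab <- stage("input", {
    if (!is.null(config$input))
      readCohort(config$input, schema = config$schema,
                 snps = config$snps %||% names(config$codingSchemes))
    else
      simulateCohort(config$design, seed = config$seed)
  })
  snps <- attr(tab, "snps")

  coded <- stage("qc", {
    t2 <- codeGenotypes(tab, config$codingSchemes[
      names(config$codingSchemes) %in% snps])
    list(tab = t2, qc = snpQcSummary(t2, snps, config$thresholds))
  })
  tab <- coded$tab
  report$qc <- coded$qc

  numeric_vars <- intersect(
    c("age", "parental_education", "parental_occupation",
      "monthly_income", "home_supervision", "reading"), names(tab))
  em <- NULL
  tab <- stage("imputation", {
    if (config$emImputation &&
        any(is.na(as.matrix(as.data.frame(tab)[numeric_vars])))) {
      em <- emImpute(tab, numeric_vars)
      report$imputation <- list(iterations = em$iterations,
                                n_imputed = em$n_imputed,
                                loglik_first = em$loglik[1],
                                loglik_last = em$loglik[em$iterations])
      em$data
    } else {
      report$imputation <- list(iterations = 0L, n_imputed = 0L)
      tab
    }
  })

  d <- stage("standardization", {
    d <- as.data.frame(tab)
    d$pe_z <- .z(d$parental_education)
    d$po_z <- .z(d$parental_occupation)
    d$mi_z <- .z(d$monthly_income)
    d$hs_z <- .z(d$home_supervision)
    d$reading_z <- .z(d$reading)
    for (s in snps) {
      cd <- d[[paste0(s, "_code")]]
      d[[paste0(s, "_z")]] <- if (sd(cd, na.rm = TRUE) > 0) .z(cd) else cd
    }
    d
  })

  corr_vars <- c("gender", "age", "pe_z", "po_z", "mi_z", "hs_z",
                 paste0(snps, "_z"), "reading_z")
  report$correlations <- stage("correlations",
                               correlationReport(d, corr_vars))

  covars <- c("gender", "age", "pe_z", "po_z", "mi_z")
  snp_z <- paste0(snps, "_z")
  inter <- paste0("hs_z*", snp_z)
  hier <- stage("hierarchical_regression", {
    hierarchicalBlocks("reading_z",
                       list(covars,
                            c(covars, "hs_z", snp_z),
                            c(covars, "hs_z", snp_z, inter)),
                       d)
  })
  report$hierarchical <- hier

  ros <- stage("ros", {
    fit3 <- hier$fits[[3]]
    focal_z <- paste0(config$riskSnp, "_z")
    # Holm-corrected interaction p-values from the Z-coded grid
    holm <- holmCorrection(vapply(inter, function(tm) fit3$p[[tm]],
                                  numeric(1)),
                           alpha = config$alpha)
    # focal-SNP diagnostics use the risk-indicator coding (1 = risk/
    # plastic), so the product coefficient is the risk-group slope
    # excess B3 - B1 and the "good side" orientation is its sign
    d$risk <- as.integer(d[[config$riskSnp]] == config$riskGenotype)
    risk_fit <- fitOls("reading_z",
                       c(covars, "hs_z", "risk", "hs_z*risk"), d)
    jn <- jnBoundaries(risk_fit, "hs_z", "risk", alpha = config$alpha)
    xc <- tryCatch(crossoverPoint(risk_fit, moderator = "risk",
                                  focal = "hs_z"),
                   error = function(e) NA_real_)
    isign <- sign(risk_fit$coef[["hs_z*risk"]])
    rng <- if (config$poiRange == "observed") range(d$hs_z)
           else mean(d$hs_z) + c(-2, 2) * sd(d$hs_z)
    poi <- if (is.na(xc)) NULL else
      suppressWarnings(poiIndex(xc, rng, interactionSign = isign))
    pa <- if (is.na(xc)) NULL else
      paIndex(xc, x = d$hs_z, mode = config$paMode,
              interactionSign = isign)
    nl <- nonlinearityProbe("reading_z", "hs_z", "risk",
                            covariates = covars, data = d,
                            alpha = config$alpha)
    ss <- simpleSlopes(risk_fit, "hs_z", "risk", levels = c(0, 1),
                       labels = c("non-risk", "risk/plastic"))
    list(jn = jn, crossover = xc, poi = poi, pa = pa,
         nonlinearity = nl, holm = holm, simple_slopes = ss,
         zcoded_fit = fit3, risk_fit = risk_fit)
  })
  report$ros <- ros

  reparam <- stage("reparam", {
    grp <- as.integer(d[[config$riskSnp]] == config$riskGenotype)
    selectModel(d, y = "reading_z", x = "hs_z", group = grp,
                covariates = covars, alpha = config$alpha,
                countCrossover = config$countCrossover)
  })
  report$reparam <- reparam
  report$selected <- reparam$selected
  report$interpretation <- sprintf(
    "The %s (model %s) best describes the genotype-by-environment pattern%s.",
    .reparam_models[[reparam$selected]]$label, reparam$selected,
    if (reparam$selected %in% c("c", "d"))
      ": the risk genotype is disproportionately harmed by adverse environments"
    else if (reparam$selected %in% c("e", "f"))
      ": the risk genotype disproportionately benefits from supportive environments"
    else ": the risk genotype responds more to both adverse and supportive environments")
  report$data <- d
  class(report) <- "RunReport"

  if (!is.null(config$outDir)) writeReport(report, config$outDir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.RunReport <- function(x, ...) {
  cat("Gene-environment pipeline report (seed", x$meta$seed, ")\n")
  cat("  n =", nrow(x$data), "| SNPs passing QC:",
      sum(x$qc$pass_all), "/", nrow(x$qc), "\n")
  cat("  selected model:", x$selected, "\n")
  cat("  ", x$interpretation, "\n")
  invisible(x)
}

# numbers-only view of a report for JSON serialization
.report_json <- function(report) {
  ros <- report$ros
  list(
    meta = report$meta,
    qc = report$qc[setdiff(names(report$qc), "reports")],
    imputation = report$imputation,
    correlations = list(variables = report$correlations$variables,
                        mean = report$correlations$mean,
                        sd = report$correlations$sd,
                        r = report$correlations$r,
                        p = report$correlations$p),
    hierarchical = list(
      steps = report$hierarchical$steps,
      model3 = list(terms = report$hierarchical$fits[[3]]$terms,
                    beta = report$hierarchical$fits[[3]]$beta,
                    t = report$hierarchical$fits[[3]]$t,
                    p = report$hierarchical$fits[[3]]$p)),
    ros = list(jn_lower = ros$jn$lower, jn_upper = ros$jn$upper,
               t_crit = ros$jn$t_crit,
               classification = ros$jn$classification_obs,
               crossover = ros$crossover,
               poi = if (!is.null(ros$poi)) ros$poi$poi else NA,
               pa = if (!is.null(ros$pa)) ros$pa$pa else NA,
               p_x2 = ros$nonlinearity$p_x2,
               p_zx2 = ros$nonlinearity$p_zx2,
               p_xz_augmented = ros$nonlinearity$p_xz,
               holm = as.data.frame(ros$holm)),
    reparam = list(table = report$reparam$table,
                   selected = report$reparam$selected,
                   rationale = report$reparam$rationale),
    interpretation = report$interpretation)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (machine-readable, deterministic for a given
#' config and seed), `report.md` and `tables/*.csv` (descriptive
#' correlations, hierarchical grid, six-model comparison).
#'
#' @param report a `RunReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(file.path(dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(.report_json(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  md <- c("# Gene-environment interaction report", "",
          paste0("Seed: ", report$meta$seed), "",
          "## SNP quality control", "",
          utils::capture.output(print(report$qc[
            c("snp", "genotypes", "call_rate", "maf", "hwe_p", "pass_all")])),
          "", "## Descriptive correlations", "",
          formatCorrelationMarkdown(report$correlations),
          "", "## Hierarchical regression", "",
          formatHierarchicalMarkdown(report$hierarchical),
          "", "## Regions of significance", "",
          utils::capture.output(print(report$ros$jn)),
          if (!is.null(report$ros$poi))
            utils::capture.output(print(report$ros$poi)),
          if (!is.null(report$ros$pa))
            utils::capture.output(print(report$ros$pa)),
          utils::capture.output(print(report$ros$nonlinearity)),
          "", "## Six-model crossover comparison", "",
          formatComparisonMarkdown(report$reparam),
          "", paste0("**", report$interpretation, "**"))
  writeLines(md, file.path(dir, "report.md"))
  renderTables(report, file.path(dir, "tables"))
  invisible(dir)
}

#' Write the three report tables as CSV
#'
#' Correlation matrix, hierarchical regression grid (standardized beta
#' and t per block) and the six-model comparison.
#'
#' @param report a `RunReport`.
#' @param dir output directory.
#' @return character vector of the files written, invisibly.
#' @export
renderTables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "correlations.csv")
  writeCorrelationCsv(report$correlations, f1)
  f2 <- file.path(dir, "hierarchical.csv")
  utils::write.csv(hierarchicalGrid(report$hierarchical), f2,
                   row.names = FALSE)
  f3 <- file.path(dir, "comparison.csv")
  utils::write.csv(round_df(report$reparam$table, 10), f3,
                   row.names = FALSE)
  invisible(c(f1, f2, f3))
}

#' Hierarchical regression grid (wide layout)
#'
#' Standardized beta and t columns per block, followed by R2, F,
#' delta-R2 and delta-F rows, mirroring the conventional hierarchical
#' regression table layout.
#'
#' @param h a [hierarchicalBlocks()] result.
#' @return a data frame.
#' @export
hierarchicalGrid <- function(h) {
  terms_all <- h$fits[[length(h$fits)]]$terms[-1]
  out <- data.frame(term = c(terms_all, "R2", "F", "dR2", "dF"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(h$fits)) {
    f <- h$fits[[i]]
    beta <- t_ <- rep(NA_real_, length(terms_all))
    idx <- match(f$terms[-1], terms_all)
    beta[idx] <- f$beta[f$terms[-1]]
    t_[idx] <- f$t[f$terms[-1]]
    s <- h$steps[i, ]
    out[[paste0("beta_m", i)]] <- c(beta, s$r.squared, f$fstat$value,
                                    s$dR2, s$dF)
    out[[paste0("t_m", i)]] <- c(t_, NA, NA, NA, NA)
  }
  out
}

#' Markdown rendering of a hierarchical regression
#'
#' @param h a [hierarchicalBlocks()] result.
#' @param digits decimals.
#' @return character vector of markdown lines.
#' @export
formatHierarchicalMarkdown <- function(h, digits = 2) {
  g <- hierarchicalGrid(h)
  nb <- length(h$fits)
  hdr <- c("Variable", paste0("Model ", seq_len(nb), " beta (t)"))
  fmt <- function(b, t, p = NA) {
    if (is.na(b)) return("")
    s <- if (!is.na(p)) .stars(p) else ""
    if (is.na(t)) sprintf("%.*f%s", digits, b, s) else
      sprintf("%.*f%s (%.2f)", digits, b, s, t)
  }
  lines <- c(paste(hdr, collapse = " | "),
             paste(rep("---", nb + 1), collapse = " | "))
  terms_all <- h$fits[[nb]]$terms[-1]
  for (i in seq_along(terms_all)) {
    cells <- vapply(seq_len(nb), function(m) {
      f <- h$fits[[m]]
      tm <- terms_all[i]
      if (!tm %in% f$terms) "" else fmt(f$beta[[tm]], f$t[[tm]], f$p[[tm]])
    }, "")
    lines <- c(lines, paste(c(terms_all[i], cells), collapse = " | "))
  }
  statrow <- function(lbl, get) paste(
    c(lbl, vapply(seq_len(nb), get, "")), collapse = " | ")
  lines <- c(lines,
    statrow("R^2", function(m) sprintf("%.3f", h$steps$r.squared[m])),
    statrow("F", function(m) {
      f <- h$fits[[m]]
      sprintf("%.2f%s", f$fstat$value, .stars(f$fstat$p)) }),
    statrow("dR^2", function(m) sprintf("%.3f", h$steps$dR2[m])),
    statrow("dF", function(m) if (is.na(h$steps$dF[m])) "" else
      sprintf("%.2f%s", h$steps$dF[m], .stars(h$steps$p[m]))),
    "", "Note: * p < 0.05, ** p < 0.01, *** p < 0.001.")
  lines
}
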