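#' @importFrom stats qnorm rnorm runif
NULL

# Generating parameters by true interaction model.  Slopes and
# intercepts follow the six-model taxonomy: strong models constrain the
# non-risk-group slope B1 to 0; diathesis-stress models place the
# crossover at the sample maximum of the environment, vantage
# sensitivity at the minimum, differential susceptibility inside the
# observed range.
.model_defaults <- list(
  a    = list(B0 = 4.97, B1 = 0.00, B3 = 0.31,  crossover = 0.39),
  b    = list(B0 = 5.01, B1 = 0.07, B3 = 0.31,  crossover = 0.49),
  c    = list(B0 = 4.93, B1 = 0.00, B3 = 0.14,  crossover = "max"),
  d    = list(B0 = 5.14, B1 = 0.10, B3 = 0.21,  crossover = "max"),
  e    = list(B0 = 4.97, B1 = 0.00, B3 = -0.01, crossover = "min"),
  f    = list(B0 = 4.42, B1 = 0.13, B3 = 0.11,  crossover = "min"),
  null = list(B0 = 0.00, B1 = 0.00, B3 = 0.00,  crossover = 0)
)

# Latent (Gaussian copula) correlation targets among gender, age,
# parental education, parental occupation, monthly income and the home
# supervision factor, in that order.
.covariate_latent_cor <- function() {
  v <- c("gender", "age", "pe", "po", "mi", "hs")
  R <- diag(6); dimnames(R) <- list(v, v)
  set <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set("gender", "age", -0.06); set("gender", "pe", 0.05)
  set("gender", "po", -0.11);  set("gender", "mi", 0.03)
  set("gender", "hs", 0.04)
  set("age", "pe", -0.04); set("age", "po", -0.17)
  set("age", "mi", -0.02); set("age", "hs", -0.01)
  set("pe", "po", -0.04); set("pe", "mi", -0.36); set("pe", "hs", 0.11)
  set("po", "mi", -0.06); set("po", "hs", 0.00)
  set("mi", "hs", 0.11)
  R
}

#' Simulation design for a synthetic reading-achievement cohort
#'
#' Describes a cohort of `n` children with three DYX1C1 SNPs, a
#' five-item home-supervision scale, demographic covariates and a
#' reading outcome generated from the two-group crossover regression
#' under a chosen true interaction model.
#'
#' Defaults emulate the study conditions this generator is calibrated
#' to: n = 745 fourth/fifth graders, genotype relative frequencies
#' rs3743205 CT 33 / TT 712, rs11629841 GT 155 / TT 590, rs8040756
#' GG 539 / AG 189 / AA 17 (all over 745), covariate correlations
#' induced by a Gaussian copula with the published descriptive
#' correlations as latent targets, and effect sizes from the weak
#' diathesis-stress fit (B1 = 0.10, B3 = 0.21, crossover at the sample
#' maximum of standardized home supervision).
#'
#' The default residual SD of 0.865 is derived from the default effect
#' sizes: the systematic component has variance ~0.20 (dominated by
#' age, 0.52^2 * var(age) ~ 0.129, plus ~0.03 from the ordinal
#' covariates, ~0.02 from the genotype-specific slopes and the
#' group-intercept offset at the boundary crossover), so sigma^2 =
#' 0.748 puts the crossover-model R^2 at about 0.214.
#'
#' @param n number of children (>= 10).
#' @param trueModel one of `"a"`..`"f"` (strong/weak differential
#'   susceptibility, diathesis-stress, vantage sensitivity) or
#'   `"null"` (no genotype or environment effect).
#' @param params optional named list overriding `B0`, `B1`, `B3`,
#'   `B4`..`B8` (gender, age, parental education, parental occupation,
#'   monthly income effects).
#' @param crossover `"max"`, `"min"` or a numeric value on the
#'   standardized environment scale; `NULL` takes the model default.
#' @param genotypeFreqs named list of genotype-probability vectors.
#' @param riskSnp,riskGenotype SNP and call defining the risk/plastic
#'   group (slope B3).
#' @param residualSd residual standard deviation of the outcome.
#' @param missingRates optional named vector of MCAR rates applied by
#'   [simulateCohort()] via [injectMissing()].
#' @param seed default RNG seed for [simulateCohort()].
#' @return a `SimulationDesign` list.
#' @export
simulationDesign <- function(n = 745, trueModel = "d", params = NULL,
                             crossover = NULL,
                             genotypeFreqs = list(
                               rs3743205  = c(CT = 33, TT = 712) / 745,
                               rs11629841 = c(GT = 155, TT = 590) / 745,
                               rs8040756  = c(GG = 539, AG = 189, AA = 17) / 745),
                             riskSnp = "rs11629841", riskGenotype = "GT",
                             residualSd = 0.865, missingRates = NULL,
                             seed = 20231027) {
  trueModel <- match.arg(trueModel, names(.model_defaults))
  if (n < 10) stop("n must be at least 10")
  if (residualSd <= 0) stop("residualSd must be positive")
  for (s in names(genotypeFreqs)) {
    f <- genotypeFreqs[[s]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
      stop("genotype frequencies for ", s, " must be non-negative and sum to 1")
  }
  if (!is.null(missingRates) && any(missingRates >= 1 | missingRates < 0))
    stop("missing rates must lie in [0, 1)")
  def <- .model_defaults[[trueModel]]
  p <- list(B0 = def$B0, B1 = def$B1, B3 = def$B3,
            B4 = 0.08, B5 = -0.52, B6 = 0.10, B7 = 0.14, B8 = 0.01)
  if (trueModel == "null") p[c("B4", "B5", "B6", "B7", "B8")] <- list(0, 0, 0, 0, 0)
  if (!is.null(params)) p[names(params)] <- params
  if (is.null(crossover)) crossover <- def$crossover
  structure(list(n = n, trueModel = trueModel, params = p,
                 crossover = crossover, genotypeFreqs = genotypeFreqs,
                 riskSnp = riskSnp, riskGenotype = riskGenotype,
                 residualSd = residualSd, missingRates = missingRates,
                 seed = seed),
            class = "SimulationDesign")
}

# quantile transform of a uniform through the two-grade age mixture
.age_from_u <- function(u, p4 = 379 / 745) {
  u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
  g4 <- u <= p4
  age <- numeric(length(u))
  age[g4] <- qnorm(pmin(pmax(u[g4] / p4, 1e-9), 1 - 1e-9), 9.33, 0.52)
  age[!g4] <- qnorm(pmin(pmax((u[!g4] - p4) / (1 - p4), 1e-9), 1 - 1e-9),
                    10.25, 0.49)
  age
}

# discretize a standard-normal latent to ordinal levels with the given
# marginal probabilities
.ordinal_from_latent <- function(z, probs) {
  cuts <- qnorm(cumsum(probs)[-length(probs)])
  findInterval(z, cuts) + 1L
}

#' Simulate a cohort with known ground truth
#'
#' Draws genotypes multinomially, covariates through a Gaussian copula
#' (ordinals discretized to their declared ranges), five 1-5 home
#' supervision items sharing a common factor (inter-item correlation
#' 0.375, so Cronbach's alpha of the latent items is ~0.75), and the
#' reading outcome from the two-group crossover mean function
#' \deqn{Y = B0 + B_g (X - C) + B4 G + B5 A + B6 Z_{PE} + B7 Z_{PO} +
#'   B8 Z_{MI} + \epsilon}
#' with \eqn{B_g = B1} in the non-risk group and \eqn{B3} in the
#' risk/plastic group, X the sample-standardized home-supervision
#' composite and C resolved against the realized sample ("max"/"min"
#' use the observed extremes of X).
#'
#' @param design a [simulationDesign()].
#' @param seed RNG seed (default: the design's); the same seed always
#'   yields the identical table.
#' @return a [cohortTable()] with a `truth` attribute recording every
#'   generating parameter, the resolved crossover and the seed.
#' @export
simulateCohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "SimulationDesign"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n
  R <- .covariate_latent_cor()
  lat <- MASS::mvrnorm(n, mu = rep(0, ncol(R)), Sigma = R)
  colnames(lat) <- colnames(R)

  gender <- as.integer(lat[, "gender"] > 0) + 1L
  age <- .age_from_u(pnorm(lat[, "age"]))
  pe <- .ordinal_from_latent(lat[, "pe"],
                             c(0.05, 0.15, 0.30, 0.25, 0.15, 0.10))
  po <- .ordinal_from_latent(lat[, "po"],
                             c(0.05, 0.08, 0.10, 0.12, 0.15,
                               0.15, 0.12, 0.10, 0.08, 0.05))
  mi <- .ordinal_from_latent(lat[, "mi"], c(0.10, 0.25, 0.30, 0.20, 0.15))

  # five parallel items: latent inter-item correlation 0.416, so that
  # after 5-level discretization (attenuation ~0.90) the observed
  # inter-item r is ~0.375 and Cronbach's alpha ~0.75
  load <- sqrt(0.416)
  # left-skewed item marginals: most parents report frequent
  # supervision, so the standardized composite has a long lower tail
  # (observed extremes near -4 and +1.9) and a ceiling on the right
  item_probs <- c(0.04, 0.08, 0.20, 0.40, 0.28)
  hs_items <- sapply(1:5, function(j)
    .ordinal_from_latent(load * lat[, "hs"] +
                           sqrt(1 - load^2) * rnorm(n), item_probs))
  colnames(hs_items) <- paste0("hs", 1:5)
  hs_comp <- rowSums(hs_items)

  geno <- lapply(design$genotypeFreqs, function(f)
    sample(names(f), n, replace = TRUE, prob = f))

  zs <- function(v) (v - mean(v)) / sd(v)
  x <- zs(hs_comp)
  cx <- design$crossover
  cx_value <- if (identical(cx, "max")) max(x) else
    if (identical(cx, "min")) min(x) else as.numeric(cx)
  risk <- as.integer(geno[[design$riskSnp]] == design$riskGenotype)
  p <- design$params
  slope <- ifelse(risk == 1L, p$B3, p$B1)
  y <- p$B0 + slope * (x - cx_value) + p$B4 * gender + p$B5 * age +
    p$B6 * zs(pe) + p$B7 * zs(po) + p$B8 * zs(mi) +
    rnorm(n, 0, design$residualSd)

  df <- data.frame(child_id = sprintf("C%04d", seq_len(n)),
                   gender = gender, age = age,
                   parental_education = pe, parental_occupation = po,
                   monthly_income = mi, hs_items, reading = y,
                   stringsAsFactors = FALSE)
  for (s in names(geno)) df[[s]] <- geno[[s]]
  tab <- cohortTable(df, snps = names(geno), validate = FALSE)
  tab$home_supervision <- hs_comp

  truth <- c(p, list(trueModel = design$trueModel,
                     crossover = cx, crossover_value = cx_value,
                     residualSd = design$residualSd,
                     riskSnp = design$riskSnp,
                     riskGenotype = design$riskGenotype,
                     n = n, seed = seed,
                     x_standardized = x, risk_group = risk))
  attr(tab, "truth") <- truth
  if (!is.null(design$missingRates))
    tab <- injectMissing(tab, design$missingRates,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  tab
}

#' Apply a missing-completely-at-random mask
#'
#' @param table a [cohortTable()] (or any data frame).
#' @param rates named vector of per-variable missingness proportions in
#'   `[0, 1)`.
#' @param seed optional RNG seed; the same seed reproduces the mask.
#' @return the table with the selected cells set to `NA`.
#' @export
injectMissing <- function(table, rates, seed = NULL) {
  if (any(rates >= 1 | rates < 0)) stop("missing rates must lie in [0, 1)")
  stopifnot(all(names(rates) %in% names(table)))
  if (!is.null(seed)) set.seed(seed)
  for (v in names(rates)) {
    if (rates[[v]] == 0) next
    mask <- runif(nrow(table)) < rates[[v]]
    table[[v]][mask] <- NA
  }
  table
}
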