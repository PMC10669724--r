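# Small in-code fixtures shared across test files.

# a minimal well-formed cohort data frame (no genotypes unless asked)
toy_cohort_df <- function(n = 6, snps = FALSE) {
  set.seed(99)
  d <- data.frame(
    child_id = sprintf("K%02d", seq_len(n)),
    gender = rep(c(1, 2), length.out = n),
    age = seq(9, 10.5, length.out = n),
    parental_education = rep(1:3, length.out = n),
    parental_occupation = rep(c(2, 5, 8), length.out = n),
    monthly_income = rep(c(1, 3, 5), length.out = n),
    home_supervision = seq(10, 25, length.out = n),
    reading = seq(-1, 1, length.out = n),
    stringsAsFactors = FALSE)
  if (snps) {
    d$rs3743205 <- rep(c("CT", "TT", "TT"), length.out = n)
    d$rs11629841 <- rep(c("GT", "TT"), length.out = n)
    d$rs8040756 <- rep(c("GG", "AG", "AA"), length.out = n)
  }
  d
}

write_toy_csv <- function(d, path = tempfile(fileext = ".csv")) {
  utils::write.csv(d, path, row.names = FALSE, na = "")
  path
}

# transform a two-column matrix so its sample covariance is exactly S
with_exact_cov <- function(n, S, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * ncol(S)), n)
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(cov(x)))   # sample covariance = identity
  x %*% chol(S)
}

# standardized cohort columns ready for crossover fits
sim_analysis_frame <- function(seed, design = simulationDesign()) {
  tab <- simulateCohort(design, seed = seed)
  tr <- attr(tab, "truth")
  d <- as.data.frame(tab)
  zs <- function(v) (v - mean(v)) / sd(v)
  d$x <- tr$x_standardized
  d$pe_z <- zs(d$parental_education)
  d$po_z <- zs(d$parental_occupation)
  d$mi_z <- zs(d$monthly_income)
  d$risk <- tr$risk_group
  attr(d, "truth") <- tr
  d
}

covars5 <- c("gender", "age", "pe_z", "po_z", "mi_z")
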