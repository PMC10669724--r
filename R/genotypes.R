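#' Genotype coding scheme
#'
#' An injective map from genotype call strings to integer codes for one
#' SNP, e.g. additive coding `GG = -1, AG = 0, AA = 1` or a two-level
#' heterozygote-carrier coding `CT = 0, TT = 1`.
#'
#' @param snp SNP name (e.g. `"rs8040756"`).
#' @param mapping named integer vector: names are valid call strings,
#'   values the numeric codes.
#' @return a `GenotypeCodingScheme`.
#' @export
codingScheme <- function(snp, mapping) {
  mapping <- stats::setNames(as.numeric(mapping), names(mapping))
  if (any(mapping != round(mapping)))
    stop("genotype codes must be integers")
  if (is.null(names(mapping)) || any(names(mapping) == ""))
    stop("mapping must be a fully named vector of calls")
  if (anyDuplicated(names(mapping)))
    stop("duplicate call strings in mapping")
  if (anyDuplicated(mapping))
    stop("mapping must be injective over valid calls")
  structure(list(snp = snp, mapping = mapping,
                 calls = names(mapping)),
            class = "GenotypeCodingScheme")
}

#' @export
print.GenotypeCodingScheme <- function(x, ...) {
  cat("Coding scheme for", x$snp, "--",
      paste(sprintf("%s = %g", names(x$mapping), x$mapping),
            collapse = ", "), "\n")
  invisible(x)
}

#' Default DYX1C1 SNP coding schemes
#'
#' rs3743205: CT = 0, TT = 1; rs11629841: GT = 0, TT = 1;
#' rs8040756: GG = -1, AG = 0, AA = 1 (additive).
#'
#' @return named list of [codingScheme()] objects.
#' @export
defaultCodingSchemes <- function() {
  list(
    rs3743205  = codingScheme("rs3743205",  c(CT = 0, TT = 1)),
    rs11629841 = codingScheme("rs11629841", c(GT = 0, TT = 1)),
    rs8040756  = codingScheme("rs8040756",  c(GG = -1, AG = 0, AA = 1))
  )
}

#' Apply genotype coding schemes to a cohort table
#'
#' Adds one numeric column `<snp>_code` per scheme.  Calls not covered
#' by a scheme become missing with a warning (lenient, default) or an
#' error (`strict = TRUE`).
#'
#' @param table a [cohortTable()] with string genotype columns.
#' @param schemes list of [codingScheme()] objects (default:
#'   [defaultCodingSchemes()] restricted to columns present).
#' @param strict error on unmapped calls instead of blanking them?
#' @return the table with the numeric code columns appended.
#' @export
codeGenotypes <- function(table, schemes = NULL, strict = FALSE) {
  if (is.null(schemes)) {
    schemes <- defaultCodingSchemes()
    schemes <- schemes[names(schemes) %in% names(table)]
  }
  for (sc in schemes) {
    if (!sc$snp %in% names(table))
      stop("genotype column '", sc$snp, "' not in table")
    calls <- as.character(table[[sc$snp]])
    unknown <- !is.na(calls) & !calls %in% sc$calls
    if (any(unknown)) {
      bad <- unique(calls[unknown])
      if (strict)
        stop("unmapped genotype call(s) for ", sc$snp, ": ",
             paste(bad, collapse = ", "))
      warning(sum(unknown), " unmapped call(s) for ", sc$snp, " (",
              paste(bad, collapse = ", "), ") set to missing")
    }
    codes <- unname(sc$mapping[match(calls, sc$calls)])
    table[[paste0(sc$snp, "_code")]] <- codes
  }
  table
}

#' SNP quality-control thresholds
#'
#' @param minCallRate minimum genotyping call rate (default 0.95).
#' @param minMaf minimum minor allele frequency, exclusive (default 0.05).
#' @param minHweP minimum Hardy-Weinberg p-value, exclusive (default 0.01).
#' @return a `QcThresholds` list.
#' @export
qcThresholds <- function(minCallRate = 0.95, minMaf = 0.05,
                         minHweP = 0.01) {
  for (v in c(minCallRate, minMaf, minHweP))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("all QC thresholds must lie in (0, 1)")
  structure(list(minCallRate = minCallRate, minMaf = minMaf,
                 minHweP = minHweP), class = "QcThresholds")
}

# split two-character diploid calls into an allele count table
.allele_counts <- function(calls) {
  calls <- calls[!is.na(calls)]
  al <- strsplit(calls, "")
  if (any(lengths(al) != 2L))
    stop("genotype calls must be two-character diploid strings")
  table(factor(unlist(al)))
}

#' Hardy-Weinberg chi-square test (1 df, no continuity correction)
#'
#' Compares observed biallelic genotype counts with expectations
#' \eqn{np^2, 2npq, nq^2} from the estimated allele frequency.
#'
#' @param nAA,nAa,naa genotype counts (homozygous major, heterozygous,
#'   homozygous minor).
#' @return list with `chisq`, `p`, `df`, expected counts.
#' @export
hweChisqTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) stop("no genotype counts")
  pA <- (2 * nAA + nAa) / (2 * n)
  qa <- 1 - pA
  if (pA == 0 || qa == 0)
    return(list(chisq = NA_real_, p = NA_real_, df = 1L,
                expected = c(nAA, nAa, naa), monomorphic = TRUE))
  e <- n * c(pA^2, 2 * pA * qa, qa^2)
  chisq <- sum((c(nAA, nAa, naa) - e)^2 / e)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L, expected = e, monomorphic = FALSE)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test enumerating all heterozygote counts
#' compatible with the observed allele counts; the p-value sums the
#' probabilities of configurations no more probable than the observed
#' one.  Preferable to the chi-square when a genotype class is rare.
#'
#' @inheritParams hweChisqTest
#' @return list with `p` and the observed heterozygote count.
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0)
    return(list(p = NA_real_, nAa = nAa, monomorphic = TRUE))
  rare <- min(nA, na)
  het_values <- seq(rare %% 2, rare, by = 2)
  # P(h het | allele counts) ~ 2^h / (hAA! h! haa!) up to a constant,
  # with hAA = (nA - h)/2 homozygous-common, haa = (na - h)/2 rare
  logp <- vapply(het_values, function(h) {
    h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
      lgamma((na - h) / 2 + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs_het <- nAa
  p <- sum(pr[pr <= pr[match(obs_het, het_values)] * (1 + 1e-12)])
  list(p = p, nAa = nAa, monomorphic = FALSE)
}

#' Per-SNP quality-control report
#'
#' Computes genotype counts and percentages, call rate, allele
#' frequencies, minor allele frequency and a Hardy-Weinberg test, with
#' pass/fail flags against the supplied thresholds.
#'
#' @param table a [cohortTable()].
#' @param snp genotype column name.
#' @param thresholds a [qcThresholds()].
#' @param hweMethod `"chisq"` (default) or `"exact"`.
#' @return a `SnpQcReport` list.
#' @export
snpQc <- function(table, snp, thresholds = qcThresholds(),
                  hweMethod = c("chisq", "exact")) {
  hweMethod <- match.arg(hweMethod)
  stopifnot(snp %in% names(table))
  calls <- as.character(table[[snp]])
  n <- length(calls)
  obs <- calls[!is.na(calls)]
  if (!length(obs)) stop("no non-missing calls for ", snp)
  counts <- table(factor(obs))
  pct <- 100 * as.numeric(counts) / length(obs)
  call_rate <- length(obs) / n
  ac <- .allele_counts(calls)
  freqs <- as.numeric(ac) / sum(ac)
  names(freqs) <- names(ac)
  maf <- if (length(freqs) == 1L) 0 else min(freqs)
  # order genotype classes as (major hom, het, minor hom) for HWE
  hwe <- NULL
  if (length(freqs) == 2L) {
    alleles <- names(freqs)[order(-freqs)]
    g_major <- paste0(alleles[1], alleles[1])
    g_minor <- paste0(alleles[2], alleles[2])
    het_names <- c(paste0(alleles[1], alleles[2]),
                   paste0(alleles[2], alleles[1]))
    nAA <- sum(obs == g_major)
    nAa <- sum(obs %in% het_names)
    naa <- sum(obs == g_minor)
    hwe <- if (hweMethod == "chisq") hweChisqTest(nAA, nAa, naa)
           else hweExactTest(nAA, nAa, naa)
  }
  hwe_p <- if (is.null(hwe)) NA_real_ else hwe$p
  res <- list(
    snp = snp, n = n,
    counts = stats::setNames(as.integer(counts), names(counts)),
    percentages = stats::setNames(round(pct, 2), names(counts)),
    call_rate = call_rate,
    allele_freqs = freqs, maf = maf,
    hwe = hwe, hwe_method = hweMethod, hwe_p = hwe_p,
    monomorphic = length(freqs) == 1L,
    pass = c(call_rate = call_rate >= thresholds$minCallRate,
             maf = maf > thresholds$minMaf,
             hwe = is.na(hwe_p) || hwe_p > thresholds$minHweP),
    thresholds = thresholds)
  res$pass_all <- all(res$pass)
  class(res) <- "SnpQcReport"
  res
}

#' @export
print.SnpQcReport <- function(x, ...) {
  cat("SNP QC report:", x$snp, " (n =", x$n, ")\n")
  for (g in names(x$counts))
    cat(sprintf("  %s = %d (%.2f%%)\n", g, x$counts[g], x$percentages[g]))
  cat(sprintf("  call rate %.4f | MAF %.4f | HWE p %s (%s)\n",
              x$call_rate, x$maf,
              ifelse(is.na(x$hwe_p), "undefined", format(x$hwe_p, digits = 3)),
              x$hwe_method))
  verdict <- ifelse(x$pass, "pass", "FAIL")
  cat("  criteria:", paste(names(x$pass), verdict, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' QC summary for several SNPs
#'
#' QC failures are reported, never silently dropped; downstream
#' analyses take an explicit SNP include-list.
#'
#' @param table a [cohortTable()].
#' @param snps genotype column names (default: the table's SNPs).
#' @param thresholds a [qcThresholds()].
#' @param hweMethod passed to [snpQc()].
#' @return data frame with one row per SNP, plus a `reports` attribute
#'   holding the full [snpQc()] objects.
#' @export
snpQcSummary <- function(table, snps = attr(table, "snps"),
                         thresholds = qcThresholds(),
                         hweMethod = "chisq") {
  reports <- lapply(snps, snpQc, table = table, thresholds = thresholds,
                    hweMethod = hweMethod)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(snp = r$snp, n = r$n,
               genotypes = paste(sprintf("%s=%d (%.2f%%)", names(r$counts),
                                         r$counts, r$percentages),
                                 collapse = "; "),
               call_rate = r$call_rate, maf = r$maf, hwe_p = r$hwe_p,
               pass_call_rate = r$pass[["call_rate"]],
               pass_maf = r$pass[["maf"]], pass_hwe = r$pass[["hwe"]],
               pass_all = r$pass_all, stringsAsFactors = FALSE)
  }))
  attr(df, "reports") <- stats::setNames(reports, snps)
  df
}
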