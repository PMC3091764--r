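#' Hardy-Weinberg goodness-of-fit test
#'
#' 1-df chi-square comparing observed genotype counts with (np^2, 2npq,
#' nq^2) from the sample allele frequency. Direction of deviation is read
#' from the sign of observed minus expected heterozygotes: a deficit is
#' excess homozygosity (the footprint of inbreeding or similarity-seeking
#' mate choice), a surplus excess heterozygosity. Vectorised over SNPs.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (AA = alternate-allele homozygote)
#' @return data frame: `chi2`, `p`, `direction` (`"het_excess"`,
#'   `"hom_excess"` or `"none"`), `maf`, `n`
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0)) stop("empty genotype counts")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (any(p == 0 | p == 1)) stop("monomorphic SNP: HWE test undefined")
  q <- 1 - p
  e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  o <- cbind(n_AA, n_Aa, n_aa)
  chi2 <- rowSums((o - e)^2 / e)
  dh <- n_Aa - e[, 2]
  direction <- ifelse(abs(dh) < 1e-9, "none",
                      ifelse(dh > 0, "het_excess", "hom_excess"))
  data.frame(chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             direction = direction, maf = pmin(p, q), n = n,
             stringsAsFactors = FALSE)
}

#' Cross-classify couple-similarity direction by population HWE deviation
#'
#' A SNP enters the 2x2 table iff its population-panel MAF is at least
#' `maf_min`, its couple-scan p value is below `p_threshold`, and its HWE
#' deviation p value is below `p_threshold` (the two 0.024 cutoffs combine
#' by Fisher's method to p < 0.005). Rows: couple direction (dissimilar =
#' R2 < 0, similar = R2 > 0); columns: population deviation (excess
#' heterozygosity, excess homozygosity).
#'
#' @param couple_results data frame with columns `snp`, `r2` and `p_two`
#'   (e.g. from [snp_p_values()])
#' @param hwe_results data frame with columns `snp`, `p`, `direction`,
#'   `maf` (e.g. [hwe_test()] output plus a `snp` column)
#' @param p_threshold joint significance cutoff, default 0.024
#' @param maf_min population MAF floor, default 0.01
#' @return object of class `contingency_2x2`: list with `observed` (2x2
#'   matrix), `expected`, `n_snps`
#' @export
classify_snps <- function(couple_results, hwe_results, p_threshold = 0.024,
                          maf_min = 0.01) {
  j <- match(couple_results$snp, hwe_results$snp)
  ok <- !is.na(j)
  cr <- couple_results[ok, , drop = FALSE]
  hr <- hwe_results[j[ok], , drop = FALSE]
  sel <- hr$maf >= maf_min & cr$p_two < p_threshold & hr$p < p_threshold &
    !is.na(cr$r2) & cr$r2 != 0 & hr$direction != "none"
  if (!any(sel)) stop("no SNP passes the joint thresholds")
  rows <- factor(ifelse(cr$r2[sel] > 0, "similar", "dissimilar"),
                 levels = c("dissimilar", "similar"))
  cols <- factor(hr$direction[sel], levels = c("het_excess", "hom_excess"))
  observed <- unclass(table(rows, cols))
  contingency_2x2(observed)
}

#' Construct a 2x2 contingency object
#'
#' @param observed 2x2 matrix of counts, rows = couple direction
#'   (dissimilar, similar), columns = population deviation (het excess,
#'   hom excess)
#' @return a `contingency_2x2` with independence-expected counts attached
#' @export
contingency_2x2 <- function(observed) {
  observed <- as.matrix(observed)
  stopifnot(all(dim(observed) == c(2, 2)), all(observed >= 0))
  if (is.null(rownames(observed))) {
    dimnames(observed) <- list(c("dissimilar", "similar"),
                               c("het_excess", "hom_excess"))
  }
  expected <- if (all(rowSums(observed) > 0) && all(colSums(observed) > 0)) {
    expected_counts(observed)
  } else {
    matrix(NA_real_, 2, 2, dimnames = dimnames(observed))
  }
  structure(list(observed = observed, expected = expected,
                 n_snps = sum(observed)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("2x2 couple-direction x population-HWE-deviation table\n")
  o <- x$observed; e <- x$expected
  for (i in 1:2) {
    cat(sprintf("  %-10s  %4d (%6.2f)  %4d (%6.2f)\n", rownames(o)[i],
                o[i, 1], e[i, 1], o[i, 2], e[i, 2]))
  }
  invisible(x)
}

#' Independence-expected counts of a 2x2 table
#'
#' @param table a `contingency_2x2` or a 2x2 count matrix
#' @return 2x2 matrix `E[i,j] = row_i * col_j / total`
#' @export
expected_counts <- function(table) {
  o <- if (inherits(table, "contingency_2x2")) table$observed else
    as.matrix(table)
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    stop("expected counts need positive margins")
  }
  outer(rowSums(o), colSums(o)) / sum(o)
}

#' Chi-square test of independence on a 2x2 table
#'
#' With `continuity_correction` (the default, and the form that reproduces
#' the published statistic) the Yates-corrected sum
#' ((|O - E| - 0.5)^2 / E); without, the plain (O - E)^2 / E. Referred to
#' chi-square with 1 df.
#'
#' @param table a `contingency_2x2` or 2x2 count matrix
#' @param continuity_correction apply Yates' correction (default TRUE)
#' @return list: `statistic`, `df` (1), `p`
#' @export
chi_square_2x2 <- function(table, continuity_correction = TRUE) {
  o <- if (inherits(table, "contingency_2x2")) table$observed else
    as.matrix(table)
  e <- expected_counts(o)
  if (any(e <= 0)) stop("zero expected count")
  dev <- abs(o - e)
  if (continuity_correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  list(statistic = stat, df = 1,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Odds ratio of excess homozygosity for similar vs dissimilar SNPs
#'
#' Cross-product ratio oriented as odds(hom excess | similar) /
#' odds(hom excess | dissimilar). A zero cell triggers the
#' Haldane-Anscombe +0.5 correction (flagged in the result).
#'
#' @param table a `contingency_2x2` or 2x2 count matrix (rows dissimilar,
#'   similar; columns het excess, hom excess)
#' @return list: `or`, `corrected` (logical)
#' @export
odds_ratio <- function(table) {
  o <- if (inherits(table, "contingency_2x2")) table$observed else
    as.matrix(table)
  corrected <- any(o == 0)
  if (corrected) o <- o + 0.5
  list(or = (o["similar", "hom_excess"] / o["similar", "het_excess"]) /
         (o["dissimilar", "hom_excess"] / o["dissimilar", "het_excess"]),
       corrected = corrected)
}

#' Couple-similarity vs population-homozygosity analysis, end to end
#'
#' Runs the full pipeline: per-SNP couple p values, per-SNP HWE tests on a
#' population panel, the joint-threshold 2x2 classification, chi-square and
#' odds ratio.
#'
#' @param couple_results output of [snp_p_values()] (needs `snp`, `r2`,
#'   `p_two`)
#' @param panel a `genotype_table` for the population panel (synthetic
#'   stand-in for HapMap CEU)
#' @param p_threshold,maf_min see [classify_snps()]
#' @param continuity_correction see [chi_square_2x2()]
#' @return list: `table` (`contingency_2x2`), `chi2` (list), `odds_ratio`
#'   (list), `hwe` (per-SNP data frame)
#' @export
homozygosity_link <- function(couple_results, panel, p_threshold = 0.024,
                              maf_min = 0.01, continuity_correction = TRUE) {
  d <- panel$dosages
  n2 <- colSums(d == 2, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n0 <- colSums(d == 0, na.rm = TRUE)
  poly <- (2 * n2 + n1) > 0 & (2 * n0 + n1) > 0   # both alleles observed
  hw <- hwe_test(n2[poly], n1[poly], n0[poly])
  hw$snp <- colnames(d)[poly]
  tab <- classify_snps(couple_results, hw, p_threshold, maf_min)
  chi2 <- tryCatch(chi_square_2x2(tab, continuity_correction),
                   error = function(e) list(statistic = NA_real_, df = 1,
                                            p = NA_real_))
  list(table = tab, chi2 = chi2, odds_ratio = odds_ratio(tab), hwe = hw)
}
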