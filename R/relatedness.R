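#' Identity-in-state score for a pair of diploid genotypes
#'
#' The proportion of identical variants between two individuals at one SNP:
#' 1 if both are homozygous for the same allele, 0.5 if either individual is
#' heterozygous, 0 otherwise. Vectorised; inputs must be non-missing.
#'
#' @param g1,g2 dosage vectors with entries in \{0, 1, 2\}
#' @return numeric vector of scores in \{0, 0.5, 1\}
#' @export
identity_proportion <- function(g1, g2) {
  out <- ifelse(g1 == 1 | g2 == 1, 0.5, 1 - abs(g1 - g2) / 2)
  out[is.na(g1) | is.na(g2)] <- NA_real_
  out
}

# 3x3 identity score matrix indexed by dosage + 1
IDENTITY3 <- matrix(c(1, 0.5, 0,
                      0.5, 0.5, 0.5,
                      0, 0.5, 1), 3, 3, byrow = TRUE)

# Dosage matrices for the coupled males / females, rows aligned to couples.
couple_dosages <- function(table, couples, snps = NULL) {
  idx <- couple_indices(table, couples)
  d <- table$dosages
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, table$variants$id)
    if (anyNA(snps)) stop("unknown SNP in requested set")
    d <- d[, snps, drop = FALSE]
  }
  list(gm = d[idx$male, , drop = FALSE],
       gf = d[idx$female, , drop = FALSE])
}

#' Mean identity kernel between all male x female cross pairs
#'
#' `K[i, j]` is the mean identity-in-state over SNPs (pairwise-complete)
#' between the male of couple `i` and the female of couple `j`. The diagonal
#' holds the per-couple identity Qc; any spouse re-pairing's statistics are
#' read off the kernel in O(n), which is what makes large permutation tests
#' cheap.
#'
#' @param table a `genotype_table`
#' @param couples a `couple_set`
#' @param snps SNP indices or IDs (default: all)
#' @return list with `K` (n x n mean identity) and `n_obs` (jointly observed
#'   SNP counts per cross pair)
#' @export
identity_kernel <- function(table, couples, snps = NULL) {
  cd <- couple_dosages(table, couples, snps)
  gm <- cd$gm; gf <- cd$gf
  om <- (!is.na(gm)) * 1; of <- (!is.na(gf)) * 1
  ind <- function(g, k) (!is.na(g) & g == k) * 1
  m0 <- ind(gm, 0); m1 <- ind(gm, 1); m2 <- ind(gm, 2)
  f0 <- ind(gf, 0); f1 <- ind(gf, 1); f2 <- ind(gf, 2)
  num <- tcrossprod(m0, f0) + tcrossprod(m2, f2) +
    0.5 * (tcrossprod(m1, of) + tcrossprod(om, f1) - tcrossprod(m1, f1))
  den <- tcrossprod(om, of)
  K <- num / den
  K[den == 0] <- NA
  list(K = K, n_obs = den)
}

#' Closed-form mean identity over all cross pairs (Qm)
#'
#' Per SNP, Qm is the expected identity between a random coupled male and a
#' random coupled female, computed exactly from the two sexes' genotype
#' frequency vectors (sum over the 3 x 3 genotype combinations weighted by
#' the identity score). The region-level Qm is the mean of per-SNP values
#' over SNPs with data.
#'
#' @inheritParams identity_kernel
#' @return list with `per_snp` (named numeric), `qm` (region mean),
#'   `monomorphic` (logical per SNP: Qm = 1, R1 undefined there)
#' @export
compute_qm <- function(table, couples, snps = NULL) {
  cd <- couple_dosages(table, couples, snps)
  freq3 <- function(g) {
    n <- colSums(!is.na(g))
    rbind(colSums(g == 0, na.rm = TRUE),
          colSums(g == 1, na.rm = TRUE),
          colSums(g == 2, na.rm = TRUE)) / rep(n, each = 3)
  }
  fm <- freq3(cd$gm)
  ff <- freq3(cd$gf)
  per_snp <- colSums(fm * (IDENTITY3 %*% ff))
  names(per_snp) <- colnames(cd$gm)
  mono <- !is.na(per_snp) & per_snp >= 1 - 1e-12
  list(per_snp = per_snp, qm = mean(per_snp, na.rm = TRUE),
       monomorphic = mono)
}

#' Couple relatedness coefficient R1
#'
#' R1 = (Qc - Qm) / (1 - Qm), where Qc is the mean identity-in-state between
#' spouses and Qm the mean over all male x female cross pairs. Positive R1
#' means spouses are more genetically alike than random cross-sex pairs
#' drawn from the same sample.
#'
#' @inheritParams identity_kernel
#' @return list of class `r1_result`: `scope`, `qc`, `qm`, `r1`,
#'   `per_couple` (per-couple R1), `n_couples`
#' @export
compute_r1 <- function(table, couples, snps = NULL) {
  cd <- couple_dosages(table, couples, snps)
  idm <- identity_proportion(cd$gm, cd$gf)   # NA propagates from either
  qc_i <- rowMeans(idm, na.rm = TRUE)
  qmres <- compute_qm(table, couples, snps)
  qm <- qmres$qm
  if (!is.finite(qm) || qm >= 1 - 1e-12) {
    stop("Qm = 1 over the requested SNP set; R1 undefined")
  }
  qc <- mean(qc_i, na.rm = TRUE)
  structure(list(scope = if (is.null(snps)) "genome" else "region",
                 qc = qc, qm = qm,
                 r1 = (qc - qm) / (1 - qm),
                 per_couple = (qc_i - qm) / (1 - qm),
                 n_couples = nrow(couples)),
            class = "r1_result")
}

#' @export
print.r1_result <- function(x, ...) {
  cat(sprintf("R1 (%s): %.5g  [Qc = %.5g, Qm = %.5g, %d couples]\n",
              x$scope, x$r1, x$qc, x$qm, x$n_couples))
  if (!is.null(x$p_two_sided)) {
    cat(sprintf("  permutation p (two-sided): %.4g  (%d permutations)\n",
                x$p_two_sided, x$n_perm))
  }
  invisible(x)
}

#' Spouse-reshuffling permutation test for R1
#'
#' Re-pairs females to males by uniform random permutations and recomputes
#' the couple-mean R1 each time (Qm held fixed at its observed value). The
#' two-sided p value is the proportion of permutations whose |mean R1| is at
#' least the observed |mean R1|; the bias-corrected form (b + 1)/(B + 1) is
#' also reported.
#'
#' @inheritParams identity_kernel
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return an `r1_result` with `p_two_sided` (raw proportion),
#'   `p_corrected`, `n_perm` and `perm_r1` (the null draws)
#' @export
permutation_test_r1 <- function(table, couples, snps = NULL,
                                n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  res <- compute_r1(table, couples, snps)
  ik <- identity_kernel(table, couples, snps)
  n <- nrow(couples)
  qm <- res$qm
  set.seed(seed)
  perm_r1 <- vapply(seq_len(n_perm), function(b) {
    pi <- sample.int(n)
    (mean(ik$K[cbind(seq_len(n), pi)], na.rm = TRUE) - qm) / (1 - qm)
  }, numeric(1))
  res$perm_r1 <- perm_r1
  res$n_perm <- n_perm
  res$p_two_sided <- mean(abs(perm_r1) >= abs(res$r1) - 1e-12)
  res$p_corrected <- (sum(abs(perm_r1) >= abs(res$r1) - 1e-12) + 1) /
    (n_perm + 1)
  res
}

#' Compare subsets of couples against a reference R1
#'
#' Draws `k` couples without replacement `n_draws` times and reports the
#' fraction of draws whose subset mean R1 falls below `reference_r1`. Qm is
#' held at the full-sample value (the subset only changes Qc).
#'
#' @inheritParams identity_kernel
#' @param k subset size
#' @param n_draws number of random subsets
#' @param reference_r1 external reference value of R1
#' @param seed integer seed
#' @return list: `fraction_below`, `draws` (subset mean R1 values), `k`,
#'   `reference_r1`
#' @export
subset_r1_comparison <- function(table, couples, k = 28, n_draws = 1e5,
                                 reference_r1, seed = 1) {
  n <- nrow(couples)
  if (k > n) stop("subset size k exceeds the number of couples")
  cd <- couple_dosages(table, couples)
  qc_i <- rowMeans(identity_proportion(cd$gm, cd$gf), na.rm = TRUE)
  qm <- compute_qm(table, couples)$qm
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(b) {
    (mean(qc_i[sample.int(n, k)]) - qm) / (1 - qm)
  }, numeric(1))
  list(fraction_below = mean(draws < reference_r1), draws = draws,
       k = k, reference_r1 = reference_r1)
}
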