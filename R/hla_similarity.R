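#' Allele-sharing points for one couple at one HLA gene
#'
#' One point per shared allele copy, capped at two: the multiset
#' intersection size of the two unordered allele pairs. Symmetric and
#' invariant to within-pair allele order; a homozygote against a
#' heterozygote carrying that allele scores 1.
#'
#' @param a1,a2 the first individual's allele pair (vectors recycle)
#' @param b1,b2 the second individual's allele pair
#' @return integer vector in \{0, 1, 2\}
#' @export
couple_sharing_points <- function(a1, a2, b1, b2) {
  hom <- a1 == a2
  # homozygote: copies of the single allele carried by the partner, capped
  n_hom <- pmin(2L, (b1 == a1) + (b2 == a1))
  # heterozygote: each distinct allele contributes at most one shared copy
  n_het <- pmin(1L, (b1 == a1) + (b2 == a1)) + pmin(1L, (b1 == a2) + (b2 == a2))
  as.integer(ifelse(hom, n_hom, n_het))
}

# Aligned allele matrices for couples at one gene; couples with either
# member untyped are dropped (count reported).
gene_couple_alleles <- function(hla, couples, gene) {
  g <- hla[hla$gene == gene, , drop = FALSE]
  if (!nrow(g)) stop("gene absent from HLA table: ", gene)
  im <- match(couples$male, g$sample)
  iff <- match(couples$female, g$sample)
  ok <- !is.na(im) & !is.na(iff)
  list(h1 = g$allele1[im[ok]], h2 = g$allele2[im[ok]],
       w1 = g$allele1[iff[ok]], w2 = g$allele2[iff[ok]],
       n_used = sum(ok), n_skipped = sum(!ok))
}

#' Observed HLA similarity score for one gene
#'
#' Total sharing points over couples: one point for each couple sharing one
#' allele at the gene, two points for each couple with both alleles in
#' common. Couples missing either member's typing are skipped (count
#' returned).
#'
#' @param hla an `hla_table`
#' @param couples a `couple_set`
#' @param gene gene name (e.g. `"DQA1"`)
#' @return list: `score`, `n_used`, `n_skipped`
#' @export
gene_similarity_score <- function(hla, couples, gene) {
  al <- gene_couple_alleles(hla, couples, gene)
  if (!al$n_used) stop("no couple has complete typing at ", gene)
  list(score = sum(couple_sharing_points(al$h1, al$h2, al$w1, al$w2)),
       n_used = al$n_used, n_skipped = al$n_skipped)
}

#' Anscombe-Glynn test of kurtosis
#'
#' Two-sided test that the sample kurtosis matches the normal value 3,
#' using the Anscombe-Glynn (1983) transformation of standardised b2 to an
#' approximate standard normal.
#'
#' @param x numeric sample, n >= 20
#' @return list: `b2` (sample kurtosis), `z` (standardised statistic), `p`
#'   (two-sided)
#' @export
anscombe_glynn_kurtosis_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20) stop("kurtosis test needs n >= 20")
  s2 <- mean((x - mean(x))^2)
  if (s2 <= 0) stop("degenerate (zero-variance) sample")
  b2 <- mean((x - mean(x))^4) / s2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z <- ((1 - 2 / (9 * a)) -
          ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  list(b2 = b2, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Permutation background for an HLA gene score
#'
#' Reassigns wives to husbands `n_perm` times (default 20,000) and
#' recalculates the gene score, yielding the null mean and sd used by the
#' normal approximation, plus an Anscombe-Glynn kurtosis check of the
#' background's normality.
#'
#' @inheritParams gene_similarity_score
#' @param n_perm number of reassignments
#' @param seed integer seed
#' @return list: `mean`, `sd`, `kurtosis_p`, `samples`
#' @export
permutation_background <- function(hla, couples, gene, n_perm = 20000,
                                   seed = 1) {
  stopifnot(n_perm >= 2)
  al <- gene_couple_alleles(hla, couples, gene)
  n <- al$n_used
  set.seed(seed)
  samples <- vapply(seq_len(n_perm), function(b) {
    pi <- sample.int(n)
    sum(couple_sharing_points(al$h1, al$h2, al$w1[pi], al$w2[pi]))
  }, numeric(1))
  list(mean = mean(samples), sd = stats::sd(samples),
       kurtosis_p = anscombe_glynn_kurtosis_test(samples)$p,
       samples = samples)
}

#' Normal-approximation p value for a gene score
#'
#' @param observed observed score
#' @param mean,sd background mean and sd (sd > 0)
#' @param tail `"upper"` (similarity), `"lower"` (dissimilarity) or
#'   `"two"`
#' @return the p value
#' @export
normal_approx_p <- function(observed, mean, sd,
                            tail = c("upper", "lower", "two")) {
  tail <- match.arg(tail)
  if (!is.finite(sd) || sd <= 0) stop("background sd must be positive")
  z <- (observed - mean) / sd
  switch(tail,
         upper = stats::pnorm(z, lower.tail = FALSE),
         lower = stats::pnorm(z),
         two = 2 * stats::pnorm(-abs(z)))
}

#' Full HLA allele-sharing analysis
#'
#' Per gene: observed sharing score, permutation background (mean, sd,
#' kurtosis diagnostic) and upper-/lower-tail normal p values (upper =
#' similarity, lower = dissimilarity).
#'
#' @inheritParams gene_similarity_score
#' @param genes gene names (default: all in the table)
#' @param n_perm reassignments per gene (default 20,000)
#' @param seed integer seed
#' @return data frame: `gene`, `observed_score`, `n_couples`,
#'   `background_mean`, `background_sd`, `p_upper`, `p_lower`,
#'   `kurtosis_p`
#' @export
hla_similarity_scan <- function(hla, couples, genes = NULL, n_perm = 20000,
                                seed = 1) {
  if (is.null(genes)) genes <- unique(hla$gene)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    obs <- gene_similarity_score(hla, couples, g)
    bg <- permutation_background(hla, couples, g, n_perm = n_perm,
                                 seed = seed + i)
    data.frame(gene = g, observed_score = obs$score,
               n_couples = obs$n_used,
               background_mean = bg$mean, background_sd = bg$sd,
               p_upper = normal_approx_p(obs$score, bg$mean, bg$sd, "upper"),
               p_lower = normal_approx_p(obs$score, bg$mean, bg$sd, "lower"),
               kurtosis_p = bg$kurtosis_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
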