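# Mendelian heterozygote probability indexed by (father dosage + 1,
# mother dosage + 1)
HET_PROB3 <- matrix(c(0, 0.5, 1,
                      0.5, 0.5, 0.5,
                      1, 0.5, 0), 3, 3, byrow = TRUE)

#' Mendelian offspring heterozygote probability
#'
#' Exact probability that a child of the given parental dosage pair is
#' heterozygous, from the Punnett square: 0 for identical homozygote
#' parents, 1 for opposite homozygotes, 1/2 whenever either parent is
#' heterozygous. Vectorised; symmetric in the parents.
#'
#' @param g_father,g_mother parental dosages in \{0, 1, 2\}
#' @return probability vector
#' @export
offspring_het_prob <- function(g_father, g_mother) {
  out <- HET_PROB3[cbind(as.vector(g_father) + 1, as.vector(g_mother) + 1)]
  if (is.matrix(g_father)) dim(out) <- dim(g_father)
  out
}

#' Per-SNP offspring-heterozygosity summary from parental dosage matrices
#'
#' For each SNP (column): the parental similarity (Pearson correlation of
#' the paired dosage vectors), the expected offspring heterozygote
#' frequency (mean Mendelian probability over couples), the
#' Hardy-Weinberg-expected frequency 2*p*q at the offspring allele
#' frequency (equal to the parental frequency, since Mendelian transmission
#' preserves it), and their ratio. A ratio below 1 is excess offspring
#' homozygosity.
#'
#' @param g_fathers,g_mothers couples x SNPs dosage matrices, row i of each
#'   being the two members of couple i
#' @param maf optional per-SNP generating MAF to carry through
#' @return data frame of class `offspring_summary`: `snp`, `maf`,
#'   `parental_similarity`, `het_observed`, `het_expected_hwe`, `het_ratio`
#' @export
offspring_summary <- function(g_fathers, g_mothers, maf = NA_real_) {
  stopifnot(all(dim(g_fathers) == dim(g_mothers)))
  cp <- column_pearson(g_fathers, g_mothers)
  het_obs <- colMeans(offspring_het_prob(g_fathers, g_mothers))
  p_hat <- (colMeans(g_fathers) + colMeans(g_mothers)) / 4
  het_exp <- 2 * p_hat * (1 - p_hat)
  snp <- colnames(g_fathers)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(g_fathers)))
  structure(data.frame(snp = snp, maf = maf,
                       parental_similarity = unname(cp$r),
                       het_observed = het_obs,
                       het_expected_hwe = het_exp,
                       het_ratio = het_obs / het_exp,
                       stringsAsFactors = FALSE),
            class = c("offspring_summary", "data.frame"))
}

#' Parental-similarity / offspring-heterozygosity simulation
#'
#' Generates random parental genotype pairs for `snps_per_maf` SNPs at each
#' MAF in `mafs` (defaults: 2,500 SNPs per MAF in 0.05..0.45, 1,000
#' couples), computes each SNP's parental similarity and the exact
#' Mendelian offspring heterozygote frequency, and returns the per-SNP
#' summary. Parents are independent by default; a per-SNP `rho` spec
#' induces spousal dosage correlation through the latent-normal mechanism
#' of [simulate_couples()].
#'
#' @param n_couples parental pairs per SNP (default 1,000)
#' @param mafs MAF grid (default seq(0.05, 0.45, by = 0.05))
#' @param snps_per_maf SNPs simulated at each MAF (default 2,500)
#' @param rho `NULL` (independent parents), a single correlation applied to
#'   all SNPs, or a vector recycled over the full SNP set
#' @param seed integer seed
#' @return an `offspring_summary` data frame (one row per SNP)
#' @export
run_figure_s3_sim <- function(n_couples = 1000,
                              mafs = seq(0.05, 0.45, by = 0.05),
                              snps_per_maf = 2500, rho = NULL, seed = 1) {
  set.seed(seed)
  m <- length(mafs) * snps_per_maf
  maf_vec <- rep(mafs, each = snps_per_maf)
  if (is.null(rho)) {
    rho_vec <- rep(0, m)
  } else {
    rho_vec <- rep_len(rho, m)
  }
  gf <- matrix(NA_real_, n_couples, m)
  gm <- matrix(NA_real_, n_couples, m)
  ind <- which(rho_vec == 0)
  if (length(ind)) {
    gf[, ind] <- stats::rbinom(n_couples * length(ind), 2,
                               rep(maf_vec[ind], each = n_couples))
    gm[, ind] <- stats::rbinom(n_couples * length(ind), 2,
                               rep(maf_vec[ind], each = n_couples))
  }
  cor_cols <- which(rho_vec != 0)
  if (length(cor_cols)) {
    groups <- split(cor_cols, paste(maf_vec[cor_cols], rho_vec[cor_cols]))
    for (g in groups) {
      p <- maf_vec[g[1]]
      r_lat <- calibrate_latent_rho(rho_vec[g[1]], p)
      q <- hw_probs(p)
      t1 <- stats::qnorm(q[1]); t2 <- stats::qnorm(q[1] + q[2])
      k <- length(g)
      z1 <- matrix(stats::rnorm(n_couples * k), n_couples, k)
      z2 <- r_lat * z1 +
        sqrt(1 - r_lat^2) * matrix(stats::rnorm(n_couples * k), n_couples, k)
      gf[, g] <- (z1 > t1) + (z1 > t2)
      gm[, g] <- (z2 > t1) + (z2 > t2)
    }
  }
  colnames(gf) <- colnames(gm) <- sprintf("snp%05d", seq_len(m))
  res <- offspring_summary(gf, gm, maf = maf_vec)
  res$rho <- rho_vec
  res
}

#' Association between parental similarity and offspring heterozygosity
#'
#' Correlates `parental_similarity` with `het_ratio` across SNPs. Under any
#' mixture of assortative/disassortative loci the correlation is expected
#' negative: similar parents beget homozygous children.
#'
#' @param summaries an `offspring_summary` (>= 10 SNPs)
#' @return list: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n_snps`
#' @export
similarity_het_association <- function(summaries) {
  ok <- stats::complete.cases(summaries[c("parental_similarity", "het_ratio")])
  x <- summaries$parental_similarity[ok]
  y <- summaries$het_ratio[ok]
  if (length(x) < 10) stop("need at least 10 SNPs")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n_snps = length(x))
}
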