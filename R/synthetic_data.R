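hw_probs <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# Expected spousal dosage correlation induced by thresholding a bivariate
# standard normal (latent correlation r) at the Hardy-Weinberg genotype
# quantiles of a SNP with alternate-allele frequency maf. Computed by exact
# 1-D numerical integration (no bivariate-normal CDF dependency).
latent_to_dosage_cor <- function(r, maf) {
  if (abs(r) < 1e-12) return(0)
  q <- hw_probs(maf)
  t1 <- stats::qnorm(q[1])
  t2 <- stats::qnorm(q[1] + q[2])
  s <- sqrt(max(1 - r^2, 1e-12))
  cond_mean <- function(x) {
    # E[D2 | latent1 = x]: P(middle cell) + 2 P(upper cell)
    u2 <- stats::pnorm((t2 - r * x) / s)
    u1 <- stats::pnorm((t1 - r * x) / s)
    (u2 - u1) + 2 * (1 - u2)
  }
  f <- function(x) stats::dnorm(x) * cond_mean(x)
  e12 <- stats::integrate(f, t1, t2, rel.tol = 1e-10)$value +
    2 * stats::integrate(f, t2, Inf, rel.tol = 1e-10)$value
  mu <- 2 * maf
  v <- 2 * maf * (1 - maf)
  (e12 - mu^2) / v
}

#' Calibrate the latent correlation for a target spousal dosage correlation
#'
#' The couple simulator draws, per SNP, a latent bivariate standard normal
#' per couple and thresholds each member at the Hardy-Weinberg genotype
#' quantiles, which preserves HW marginals exactly. This solves (by root
#' finding on the exact thresholded-normal moments) for the latent
#' correlation that induces a given dosage correlation `rho`.
#'
#' @param rho target spousal dosage correlation, in (-1, 1)
#' @param maf alternate (minor) allele frequency, in (0, 0.5]
#' @return the latent correlation
#' @export
calibrate_latent_rho <- function(rho, maf) {
  stopifnot(maf > 0, maf < 1)
  if (abs(rho) < 1e-12) return(0)
  lim <- 0.99995
  hi <- latent_to_dosage_cor(lim, maf)
  lo <- latent_to_dosage_cor(-lim, maf)
  if (rho > hi || rho < lo) {
    stop(sprintf(
      "dosage correlation %.3f unattainable at MAF %.3f; attainable range [%.3f, %.3f]",
      rho, maf, lo, hi))
  }
  stats::uniroot(function(r) latent_to_dosage_cor(r, maf) - rho,
                 c(-lim, lim), tol = 1e-9)$root
}

#' Specify a synthetic couple-genotype world
#'
#' @param n_couples number of couples
#' @param chromosomes named numeric vector of chromosome lengths in bp
#' @param snp_density SNPs per Mb (positions evenly spaced)
#' @param maf_spec either a single MAF, a data frame with columns `maf` and
#'   `proportion` (sampled per SNP), or a numeric vector with one MAF per SNP
#' @param assortment `NULL`, or a data frame with column `rho` plus either a
#'   `snp` column (variant IDs or indices) or `chrom`/`start`/`end` columns
#'   (1-based closed intervals); listed SNPs get the stated spousal dosage
#'   correlation, all others are independent between spouses
#' @param recomb_profile a single cM/Mb rate, or a data frame
#'   `chrom`/`start`/`end`/`rate` overriding the default of 1 inside the
#'   listed intervals
#' @param seed integer seed
#' @return a `simulation_spec` list
#' @export
simulation_spec <- function(n_couples, chromosomes = c(chr1 = 10e6),
                            snp_density = 100, maf_spec = 0.3,
                            assortment = NULL, recomb_profile = 1,
                            seed = 1) {
  stopifnot(n_couples >= 1, all(chromosomes > 0), snp_density > 0)
  if (is.data.frame(maf_spec)) {
    stopifnot(all(c("maf", "proportion") %in% names(maf_spec)))
    if (abs(sum(maf_spec$proportion) - 1) > 1e-8) {
      stop("maf_spec proportions must sum to 1")
    }
  }
  if (!is.null(assortment)) {
    stopifnot(is.data.frame(assortment), "rho" %in% names(assortment))
    if (any(abs(assortment$rho) >= 1)) stop("assortment rho must satisfy |rho| < 1")
  }
  structure(list(n_couples = n_couples, chromosomes = chromosomes,
                 snp_density = snp_density, maf_spec = maf_spec,
                 assortment = assortment, recomb_profile = recomb_profile,
                 seed = seed),
            class = "simulation_spec")
}

build_sim_map <- function(spec) {
  spacing <- 1e6 / spec$snp_density
  pieces <- lapply(names(spec$chromosomes), function(ch) {
    len <- spec$chromosomes[[ch]]
    pos <- seq(spacing, len, by = spacing)
    data.frame(chrom = ch, pos = round(pos), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  df$id <- paste0("snp_", df$chrom, "_", df$pos)
  rate <- rep(if (is.data.frame(spec$recomb_profile)) 1
              else spec$recomb_profile, nrow(df))
  if (is.data.frame(spec$recomb_profile)) {
    rp <- spec$recomb_profile
    for (k in seq_len(nrow(rp))) {
      inside <- df$chrom == rp$chrom[k] & df$pos >= rp$start[k] &
        df$pos <= rp$end[k]
      rate[inside] <- rp$rate[k]
    }
  }
  variant_map(df$id, df$chrom, df$pos, a1 = "A", a2 = "B",
              cM_per_Mb = rate)
}

resolve_assortment <- function(spec, map) {
  rho <- rep(0, nrow(map))
  a <- spec$assortment
  if (is.null(a)) return(rho)
  for (k in seq_len(nrow(a))) {
    if ("snp" %in% names(a) && !is.na(a$snp[k]) && a$snp[k] != "") {
      i <- if (is.numeric(a$snp)) a$snp[k] else match(a$snp[k], map$id)
      if (is.na(i)) stop("unknown SNP in assortment map: ", a$snp[k])
      rho[i] <- a$rho[k]
    } else {
      inside <- map$chrom == a$chrom[k] & map$pos >= a$start[k] &
        map$pos <= a$end[k]
      rho[inside] <- a$rho[k]
    }
  }
  rho
}

#' Simulate couple genotypes with controlled spousal correlation
#'
#' Each spouse's marginal genotype distribution is exactly Hardy-Weinberg at
#' the SNP's MAF. At SNPs listed in the spec's assortment map, spousal
#' dosages are correlated at the target rho via a latent bivariate normal
#' thresholded at the HW genotype quantiles (latent correlation calibrated
#' numerically); all other SNPs are independent between spouses. Output is
#' deterministic given the spec's seed.
#'
#' @param spec a [simulation_spec()]
#' @return list with elements `table` (a `genotype_table` of 2 x n_couples
#'   samples), `couples` (a `couple_set`), `map` (the `variant_map`).
#' @export
simulate_couples <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  map <- build_sim_map(spec)
  m <- nrow(map)
  n <- spec$n_couples

  maf <- spec$maf_spec
  if (is.data.frame(maf)) {
    maf <- sample(maf$maf, m, replace = TRUE, prob = maf$proportion)
  } else if (length(maf) == 1) {
    maf <- rep(maf, m)
  } else if (length(maf) != m) {
    stop("per-SNP maf_spec length (", length(maf),
         ") must equal SNP count (", m, ")")
  }
  stopifnot(all(maf > 0 & maf < 1))
  rho <- resolve_assortment(spec, map)

  gm <- matrix(NA_real_, n, m)
  gf <- matrix(NA_real_, n, m)
  null_cols <- which(rho == 0)
  if (length(null_cols)) {
    gm[, null_cols] <- stats::rbinom(n * length(null_cols), 2,
                                     rep(maf[null_cols], each = n))
    gf[, null_cols] <- stats::rbinom(n * length(null_cols), 2,
                                     rep(maf[null_cols], each = n))
  }
  assorted <- which(rho != 0)
  if (length(assorted)) {
    groups <- split(assorted, paste(maf[assorted], rho[assorted]))
    for (g in groups) {
      p <- maf[g[1]]
      r_lat <- calibrate_latent_rho(rho[g[1]], p)
      q <- hw_probs(p)
      t1 <- stats::qnorm(q[1])
      t2 <- stats::qnorm(q[1] + q[2])
      k <- length(g)
      z1 <- matrix(stats::rnorm(n * k), n, k)
      z2 <- r_lat * z1 + sqrt(1 - r_lat^2) * matrix(stats::rnorm(n * k), n, k)
      gm[, g] <- (z1 > t1) + (z1 > t2)
      gf[, g] <- (z2 > t1) + (z2 > t2)
    }
  }

  male_ids <- sprintf("M%04d", seq_len(n))
  female_ids <- sprintf("F%04d", seq_len(n))
  dos <- rbind(gm, gf)
  rownames(dos) <- c(male_ids, female_ids)
  colnames(dos) <- map$id
  sex <- stats::setNames(rep(c("male", "female"), each = n), rownames(dos))
  list(table = genotype_table(dos, sex, map),
       couples = couple_set(male_ids, female_ids),
       map = map)
}

#' Simulate couple HLA types with optional sharing bias
#'
#' Under `sharing_bias = 0` the two spouses' alleles are independent draws
#' from the gene's allele-frequency table. A positive bias is the
#' probability, per wife allele copy, of replacing the draw with a uniformly
#' chosen copy of the husband's pair; a negative bias is the probability of
#' rejecting and redrawing (from the renormalised non-husband alleles) a
#' wife allele that matches the husband.
#'
#' @param n_couples number of couples
#' @param allele_freqs named list: per gene, a named numeric vector of allele
#'   frequencies summing to 1
#' @param sharing_bias named numeric vector per gene in (-1, 1), default 0
#' @param seed integer seed
#' @return list with `hla` (an `hla_table` for samples M0001..,F0001..) and
#'   `couples` (the matching `couple_set`)
#' @export
simulate_hla <- function(n_couples, allele_freqs, sharing_bias = NULL,
                         seed = 1) {
  set.seed(seed)
  stopifnot(is.list(allele_freqs), !is.null(names(allele_freqs)))
  genes <- names(allele_freqs)
  if (is.null(sharing_bias)) {
    sharing_bias <- stats::setNames(rep(0, length(genes)), genes)
  }
  if (any(abs(sharing_bias) >= 1)) stop("sharing bias must lie in (-1, 1)")
  male_ids <- sprintf("M%04d", seq_len(n_couples))
  female_ids <- sprintf("F%04d", seq_len(n_couples))
  rows <- list()
  for (g in genes) {
    fr <- allele_freqs[[g]]
    if (abs(sum(fr) - 1) > 1e-8) stop("allele frequencies for ", g,
                                      " must sum to 1")
    alleles <- names(fr)
    b <- if (g %in% names(sharing_bias)) sharing_bias[[g]] else 0
    h1 <- sample(alleles, n_couples, replace = TRUE, prob = fr)
    h2 <- sample(alleles, n_couples, replace = TRUE, prob = fr)
    draw_wife <- function(h1i, h2i) {
      w <- sample(alleles, 1, prob = fr)
      if (b > 0 && stats::runif(1) < b) {
        w <- if (stats::runif(1) < 0.5) h1i else h2i
      } else if (b < 0 && w %in% c(h1i, h2i) && stats::runif(1) < -b) {
        others <- setdiff(alleles[fr > 0], c(h1i, h2i))
        if (!length(others)) {
          stop("negative sharing bias unattainable: husband carries every allele")
        }
        w <- sample(others, 1, prob = fr[others] / sum(fr[others]))
      }
      w
    }
    w1 <- mapply(draw_wife, h1, h2)
    w2 <- mapply(draw_wife, h1, h2)
    rows[[g]] <- data.frame(
      sample = c(male_ids, female_ids), gene = g,
      allele1 = c(h1, w1), allele2 = c(h2, w2),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  list(hla = hla_table(df$sample, df$gene, df$allele1, df$allele2),
       couples = couple_set(male_ids, female_ids))
}

#' Simulate genotype counts from a population with inbreeding
#'
#' Genotype frequencies follow the standard inbreeding model
#' (p^2 + pqF, 2pq(1-F), q^2 + pqF) for alternate-allele frequency p = `maf`.
#' Negative F (heterozygote excess, as left by disassortative mating) is
#' allowed down to the admissibility bound -min(p/q, q/p).
#'
#' @param n number of individuals
#' @param maf alternate (minor) allele frequency
#' @param f_is inbreeding coefficient
#' @param seed integer seed
#' @return named integer vector `c(n_AA, n_Aa, n_aa)`, where `n_AA` counts
#'   alternate-allele homozygotes
#' @export
simulate_inbred_population <- function(n, maf, f_is, seed = 1) {
  p <- maf; q <- 1 - maf
  lower <- -min(p / q, q / p)
  if (f_is >= 1 || f_is < lower) {
    stop(sprintf("f_is must lie in [%.3f, 1)", lower))
  }
  probs <- c(p^2 + p * q * f_is, 2 * p * q * (1 - f_is), q^2 + p * q * f_is)
  set.seed(seed)
  cnt <- as.integer(stats::rmultinom(1, n, probs))
  stats::setNames(cnt, c("n_AA", "n_Aa", "n_aa"))
}
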