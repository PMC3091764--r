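#' Fisher's method for combining p values
#'
#' Statistic -2 * sum(log p) referred to the upper tail of chi-square with
#' 2k degrees of freedom. Zero p values are clamped to the smallest positive
#' representable double (with a warning).
#'
#' @param p vector of p values in (0, 1]
#' @return list: `statistic`, `df`, `combined_p`
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  p <- p[!is.na(p)]
  if (!length(p)) stop("no non-missing p values to combine")
  if (any(p == 0)) {
    warning("p value of 0 clamped for Fisher combination")
    p[p == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(p))
  k <- length(p)
  list(statistic = stat, df = 2 * k,
       combined_p = stats::pchisq(stat, df = 2 * k, lower.tail = FALSE))
}

# SNPs of a window qualifying for the given sign mode, as row indices into
# r2res (which must carry p_one from snp_p_values()).
meta_member_rows <- function(window, r2res, map, sign_mode) {
  snp_idx <- window$snps[[1]]
  rows <- match(map$id[snp_idx], r2res$snp)
  rows <- rows[!is.na(rows)]
  rows <- rows[!is.na(r2res$r2[rows]) & r2res$r2[rows] != 0]
  switch(sign_mode,
         similar = rows[r2res$r2[rows] > 0],
         dissimilar = rows[r2res$r2[rows] < 0],
         combined = rows,
         stop("sign_mode must be similar, dissimilar or combined"))
}

#' Signed Fisher meta value of a genomic region
#'
#' Combines, by Fisher's method, the one-sided (direction-of-observed-sign)
#' p values of the region's member SNPs: `similar` mode uses SNPs with
#' R2 > 0, `dissimilar` those with R2 < 0, `combined` all non-zero-R2 SNPs.
#' A low meta value indicates an abundance of significant SNPs of the
#' requested sign.
#'
#' @param window a one-row `region_window`
#' @param r2res an `r2_result` with `p_one` (see [snp_p_values()])
#' @param map the `variant_map` the window indexes into
#' @param sign_mode `"similar"`, `"dissimilar"` or `"combined"`
#' @return list: `meta_value`, `statistic`, `n_snps_used`, `empty` (no
#'   qualifying SNPs; such regions are excluded from backgrounds)
#' @export
regional_meta <- function(window, r2res, map,
                          sign_mode = c("similar", "dissimilar", "combined")) {
  sign_mode <- match.arg(sign_mode)
  if (is.null(r2res$p_one)) stop("r2res lacks p_one; run snp_p_values() first")
  rows <- meta_member_rows(window, r2res, map, sign_mode)
  if (!length(rows)) {
    return(list(meta_value = NA_real_, statistic = NA_real_,
                n_snps_used = 0L, empty = TRUE))
  }
  fc <- fisher_combine(r2res$p_one[rows])
  list(meta_value = fc$combined_p, statistic = fc$statistic,
       n_snps_used = length(rows), empty = FALSE)
}

#' Background Fisher meta values for a candidate region
#'
#' `genome_matched` mode tiles every chromosome except the candidate's with
#' windows of the candidate's bp length (advanced by `step_bp`), drops
#' centromere-overlapping windows, and keeps windows whose mean
#' recombination rate lies on the same side of the genome-average rate as
#' the candidate's (lower if the candidate is below average, higher if
#' above); each retained window's meta value is computed in the same sign
#' mode. `permutation` mode reshuffles the spouse pairings `n_perm` times
#' and recomputes the candidate's own meta value each time (per-SNP one-
#' sided p via the t approximation).
#'
#' @param map the `variant_map`
#' @param candidate a one-row `region_window`
#' @param mode `"genome_matched"` or `"permutation"`
#' @param r2res `r2_result` with `p_one` (genome_matched mode)
#' @param table,couples genotypes and pairing (permutation mode)
#' @param sign_mode as in [regional_meta()]
#' @param step_bp tiling step for genome_matched mode (default 100 kb)
#' @param n_perm shuffle count for permutation mode (default 1000)
#' @param seed integer seed (permutation mode)
#' @return list: `metas` (background meta values), `windows` (the tiled
#'   windows, genome_matched only), `mode`. Warns when fewer than 50
#'   background values are available.
#' @export
build_background <- function(map, candidate,
                             mode = c("genome_matched", "permutation"),
                             r2res = NULL, table = NULL, couples = NULL,
                             sign_mode = "similar", step_bp = 1e5,
                             n_perm = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "genome_matched") {
    if (is.null(r2res)) stop("genome_matched mode needs genome-wide r2res")
    width <- candidate$end - candidate$start + 1
    tiles <- sliding_windows(map, width_bp = width, step_bp = step_bp,
                             min_snps = 1, mask_centromere = TRUE)
    genome_avg <- mean(tiles$mean_recomb)
    # tie-inclusive: identical to the strict "lower/higher than the
    # candidate" rule when rates vary continuously, and well defined on
    # flat recombination maps
    side <- if (candidate$mean_recomb <= genome_avg) {
      tiles$mean_recomb <= candidate$mean_recomb
    } else {
      tiles$mean_recomb >= candidate$mean_recomb
    }
    keep <- which(tiles$chrom != candidate$chrom & side)
    metas <- vapply(keep, function(i) {
      regional_meta(tiles[i, ], r2res, map, sign_mode)$meta_value
    }, numeric(1))
    metas <- metas[!is.na(metas)]
    if (length(metas) < 50) {
      warning("only ", length(metas),
              " background regions; empirical p is unstable")
    }
    list(metas = metas, windows = tiles[keep, ], mode = mode,
         genome_avg_recomb = genome_avg)
  } else {
    if (is.null(table) || is.null(couples)) {
      stop("permutation mode needs the genotype table and couples")
    }
    cd <- couple_dosages(table, couples, snps = candidate$snps[[1]])
    n <- nrow(cd$gm)
    ids <- map$id[candidate$snps[[1]]]
    set.seed(seed)
    metas <- vapply(seq_len(n_perm), function(b) {
      cp <- column_pearson(cd$gm, cd$gf[sample.int(n), , drop = FALSE])
      rr <- structure(data.frame(snp = ids, r2 = cp$r, n_used = cp$n,
                                 stringsAsFactors = FALSE),
                      class = c("r2_result", "data.frame"))
      rr <- snp_p_values(rr, "t_approx")
      w <- candidate
      w$snps <- list(seq_along(ids))
      regional_meta(w, rr, map[candidate$snps[[1]], , drop = FALSE],
                    sign_mode)$meta_value
    }, numeric(1))
    metas <- metas[!is.na(metas)]
    if (length(metas) < 50) {
      warning("only ", length(metas),
              " background values; empirical p is unstable")
    }
    list(metas = metas, mode = mode)
  }
}

#' Empirical regional p value against a background
#'
#' The fraction of background regions with a Fisher meta value smaller than
#' the candidate's. Reports the raw fraction, the bias-corrected
#' (b + 1)/(n + 1) form (used for multiplicity-corrected scans, where a
#' literal zero would be an artefact of the background's granularity), and
#' the background mean.
#'
#' @param candidate_meta the candidate region's meta value
#' @param background_metas vector of background meta values
#' @return list: `p`, `p_corrected`, `background_mean`, `n_background`
#' @export
empirical_region_p <- function(candidate_meta, background_metas) {
  stopifnot(length(background_metas) >= 1, !is.na(candidate_meta))
  b <- sum(background_metas < candidate_meta)
  n <- length(background_metas)
  list(p = b / n, p_corrected = (b + 1) / (n + 1),
       background_mean = mean(background_metas), n_background = n)
}

#' Hypothesis-neutral regional scan
#'
#' Computes the Fisher meta value of every sliding window, compares each
#' against its recombination-matched background drawn from the other
#' chromosomes' windows, and BH-adjusts the (bias-corrected) empirical p
#' values across windows.
#'
#' @param table,couples genotypes and pairing
#' @param map the `variant_map`
#' @param r2res optional precomputed `r2_result` with `p_one`; computed via
#'   the t approximation when omitted
#' @param sign_mode as in [regional_meta()]
#' @param width_bp,step_bp,min_snps window geometry (defaults 3.6 Mb /
#'   100 kb / 300)
#' @return data frame: one row per window with `chrom`, `start`, `end`,
#'   `n_snps_used`, `meta_value`, `background_mean`, `empirical_p`,
#'   `empirical_p_corrected`, `q`
#' @export
region_scan <- function(table, couples, map, r2res = NULL,
                        sign_mode = "similar", width_bp = 3.6e6,
                        step_bp = 1e5, min_snps = 300) {
  if (is.null(r2res)) {
    r2res <- snp_p_values(compute_r2(table, couples), "t_approx")
  }
  wins <- sliding_windows(map, width_bp, step_bp, min_snps,
                          mask_centromere = TRUE)
  if (!nrow(wins)) return(data.frame())
  metas <- vapply(seq_len(nrow(wins)), function(i) {
    regional_meta(wins[i, ], r2res, map, sign_mode)$meta_value
  }, numeric(1))
  nsnps <- vapply(seq_len(nrow(wins)), function(i) {
    regional_meta(wins[i, ], r2res, map, sign_mode)$n_snps_used
  }, integer(1))
  genome_avg <- mean(wins$mean_recomb)
  res <- data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
                    n_snps_used = nsnps, meta_value = metas,
                    background_mean = NA_real_, empirical_p = NA_real_,
                    empirical_p_corrected = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(wins))) {
    if (is.na(metas[i])) next
    side <- if (wins$mean_recomb[i] <= genome_avg) {
      wins$mean_recomb <= wins$mean_recomb[i]
    } else {
      wins$mean_recomb >= wins$mean_recomb[i]
    }
    bg <- metas[wins$chrom != wins$chrom[i] & side & !is.na(metas)]
    if (!length(bg)) next
    ep <- empirical_region_p(metas[i], bg)
    res$background_mean[i] <- ep$background_mean
    res$empirical_p[i] <- ep$p
    res$empirical_p_corrected[i] <- ep$p_corrected
  }
  res$q <- bh_fdr(res$empirical_p_corrected)
  res
}
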