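column_pearson <- function(gm, gf) {
  o <- (!is.na(gm) & !is.na(gf)) * 1
  xm <- ifelse(o == 1, gm, 0)
  xf <- ifelse(o == 1, gf, 0)
  n <- colSums(o)
  sm <- colSums(xm); sf <- colSums(xf)
  smm <- colSums(xm * xm); sff <- colSums(xf * xf)
  smf <- colSums(xm * xf)
  cv <- smf - sm * sf / n
  vm <- smm - sm^2 / n
  vf <- sff - sf^2 / n
  r <- cv / sqrt(vm * vf)
  r[!is.finite(r)] <- NA          # zero variance or n = 0
  r[n < 3] <- NA
  list(r = r, n = n)
}

#' Per-SNP spousal dosage correlation R2
#'
#' Pearson correlation between husbands' and wives' allele dosages
#' (0/1/2) across couples, pairwise-complete. Positive R2 = spousal
#' similarity at the SNP, negative R2 = dissimilarity. SNPs with fewer than
#' 3 complete couples or zero dosage variance in either sex are flagged
#' (`r2 = NA`) and excluded from downstream stages.
#'
#' @inheritParams identity_kernel
#' @return data frame of class `r2_result` with columns `snp`, `r2`,
#'   `n_used`
#' @export
compute_r2 <- function(table, couples, snps = NULL) {
  cd <- couple_dosages(table, couples, snps)
  cp <- column_pearson(cd$gm, cd$gf)
  structure(data.frame(snp = colnames(cd$gm), r2 = cp$r, n_used = cp$n,
                       stringsAsFactors = FALSE),
            class = c("r2_result", "data.frame"))
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard step-up FDR adjustment with enforced monotonicity,
#' order-preserving; `NA` p values stay `NA`.
#'
#' @param p numeric vector of p values in \[0, 1\]
#' @return vector of adjusted values (q values)
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Attach significance to per-SNP R2 values
#'
#' Three methods:
#' * `t_approx` — exact-null t statistic `r * sqrt((n-2)/(1-r^2))` referred
#'   to t(n-2);
#' * `perm_normal` — spouse pairings reshuffled `n_perm` times, a normal
#'   fitted to each SNP's null R2 draws, p from its tails (the method used
#'   for the PCR-genotyped SNPs, there with 200,000 shuffles);
#' * `genome_background` — a normal fitted to the genome-wide empirical R2
#'   distribution (optionally robustly, MAD for the sd), each SNP referred
#'   to that common null.
#'
#' `p_one` is one-sided in the direction of the SNP's observed sign,
#' `p_two` two-sided (the default scan output), `q` the BH adjustment of
#' `p_two`.
#'
#' @param r2res an `r2_result` from [compute_r2()]
#' @param method one of `"t_approx"`, `"perm_normal"`,
#'   `"genome_background"`
#' @param table,couples needed for `perm_normal`
#' @param n_perm permutation count for `perm_normal`
#' @param seed integer seed
#' @param robust for `genome_background`: use median/MAD instead of
#'   mean/sd
#' @return `r2res` with columns `p_one`, `p_two`, `q` added
#' @export
snp_p_values <- function(r2res, method = c("t_approx", "perm_normal",
                                           "genome_background"),
                         table = NULL, couples = NULL, n_perm = 0,
                         seed = 1, robust = FALSE) {
  method <- match.arg(method)
  r <- r2res$r2
  n <- r2res$n_used
  if (method == "t_approx") {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p_one <- stats::pt(-abs(tt), df = n - 2)
    p_two <- 2 * p_one
  } else if (method == "genome_background") {
    ok <- !is.na(r)
    mu <- if (robust) stats::median(r[ok]) else mean(r[ok])
    sdv <- if (robust) stats::mad(r[ok]) else stats::sd(r[ok])
    if (!is.finite(sdv) || sdv <= 0) stop("degenerate genome-wide R2 background")
    upper <- stats::pnorm(r, mu, sdv, lower.tail = FALSE)
    lower <- stats::pnorm(r, mu, sdv)
    p_one <- ifelse(r >= 0, upper, lower)
    p_two <- pmin(1, 2 * pmin(upper, lower))
  } else {
    if (is.null(table) || is.null(couples)) {
      stop("perm_normal needs the genotype table and couples")
    }
    if (n_perm < 2) stop("perm_normal needs n_perm >= 2")
    cd <- couple_dosages(table, couples,
                         snps = match(r2res$snp, table$variants$id))
    nc <- nrow(cd$gm)
    set.seed(seed)
    s1 <- numeric(length(r)); s2 <- numeric(length(r))
    for (b in seq_len(n_perm)) {
      rb <- column_pearson(cd$gm, cd$gf[sample.int(nc), , drop = FALSE])$r
      rb[is.na(rb)] <- 0
      s1 <- s1 + rb
      s2 <- s2 + rb^2
    }
    mu <- s1 / n_perm
    sdv <- sqrt(pmax(s2 / n_perm - mu^2, 0) * n_perm / (n_perm - 1))
    upper <- stats::pnorm(r, mu, sdv, lower.tail = FALSE)
    lower <- stats::pnorm(r, mu, sdv)
    p_one <- ifelse(r >= 0, upper, lower)
    p_two <- pmin(1, 2 * pmin(upper, lower))
  }
  r2res$p_one <- p_one
  r2res$p_two <- pmin(1, p_two)
  r2res$q <- bh_fdr(r2res$p_two)
  r2res
}

#' Sliding genomic windows over a variant map
#'
#' Windows of `width_bp` advanced by `step_bp`, anchored per chromosome at
#' the first SNP position rounded down to a step multiple; a window is kept
#' iff it lies fully within the chromosome's mapped extent and contains at
#' least `min_snps` SNPs. Windows never span chromosomes. With
#' `mask_centromere`, windows containing any centromere-flagged SNP are
#' dropped.
#'
#' @param map a `variant_map`
#' @param width_bp window width in bp (default 3.6 Mb)
#' @param step_bp step in bp (default 100 kb)
#' @param min_snps minimum SNP count per retained window (default 300)
#' @param mask_centromere drop windows overlapping centromere-flagged SNPs
#' @return data frame of class `region_window`: `chrom`, `start`, `end`
#'   (closed interval), `n_snps`, `mean_recomb`, and a list column `snps`
#'   of member SNP indices into `map`
#' @export
sliding_windows <- function(map, width_bp = 3.6e6, step_bp = 1e5,
                            min_snps = 300, mask_centromere = FALSE) {
  out <- list()
  for (ch in unique(map$chrom)) {
    w <- which(map$chrom == ch)
    pos <- map$pos[w]
    anchor <- floor(min(pos) / step_bp) * step_bp
    last_start <- max(pos) - width_bp + 1
    if (last_start < anchor) next
    starts <- seq(anchor, last_start, by = step_bp)
    for (s in starts) {
      e <- s + width_bp - 1
      inside <- w[pos >= s & pos <= e]
      if (length(inside) < min_snps) next
      if (mask_centromere && any(map$centromere[inside])) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = s, end = e, n_snps = length(inside),
        mean_recomb = mean(map$cM_per_Mb[inside]),
        stringsAsFactors = FALSE)
      attr(out[[length(out)]], "snps") <- inside
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      mean_recomb = numeric(0))
    res$snps <- list()
    class(res) <- c("region_window", "data.frame")
    return(res)
  }
  snps <- lapply(out, attr, "snps")
  res <- do.call(rbind, out)
  res$snps <- snps
  class(res) <- c("region_window", "data.frame")
  res
}

#' Define one region window from explicit coordinates
#'
#' @param map a `variant_map`
#' @param chrom chromosome label
#' @param start,end closed 1-based interval in bp
#' @return one-row `region_window` (see [sliding_windows()])
#' @export
region_window <- function(map, chrom, start, end) {
  inside <- which(map$chrom == chrom & map$pos >= start & map$pos <= end)
  res <- data.frame(chrom = chrom, start = start, end = end,
                    n_snps = length(inside),
                    mean_recomb = if (length(inside))
                      mean(map$cM_per_Mb[inside]) else NA_real_,
                    stringsAsFactors = FALSE)
  res$snps <- list(inside)
  class(res) <- c("region_window", "data.frame")
  res
}

#' Greedy LD pruning to tag SNPs
#'
#' Left-to-right sliding-window prune: a SNP is retained iff its squared
#' dosage correlation with every already-retained SNP within the trailing
#' `window_snps`-SNP window is at most `r2_threshold`.
#'
#' @param table a `genotype_table` (variants in map order)
#' @param r2_threshold maximum allowed inter-SNP r^2 (e.g. 0.25, 0.5, 0.75)
#' @param window_snps window size in SNPs (default 50)
#' @return integer vector of retained SNP indices
#' @export
ld_prune <- function(table, r2_threshold, window_snps = 50) {
  d <- table$dosages
  m <- ncol(d)
  keep <- integer(0)
  for (s in seq_len(m)) {
    near <- keep[keep > s - window_snps]
    ok <- TRUE
    for (r in near) {
      # chromosomes never share a window
      if (table$variants$chrom[r] != table$variants$chrom[s]) next
      cc <- stats::cor(d[, r], d[, s], use = "pairwise.complete.obs")
      if (is.finite(cc) && cc^2 > r2_threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, s)
  }
  keep
}
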