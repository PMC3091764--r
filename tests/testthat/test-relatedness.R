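test_that("identity-in-state scoring follows the IBS rules", {
  expect_equal(identity_proportion(c(0, 2, 1, 1, 0, 2),
                                   c(0, 2, 0, 1, 2, 0)),
               c(1, 1, 0.5, 0.5, 0, 0))
  expect_true(is.na(identity_proportion(NA, 1)))
  # symmetric in the two spouses
  g <- expand.grid(a = 0:2, b = 0:2)
  expect_equal(identity_proportion(g$a, g$b), identity_proportion(g$b, g$a))
})

test_that("closed-form Qm equals the brute-force all-cross-pairs mean", {
  # hand case: males [0,2], females [0,2] -> pairs score 1,0,0,1
  tab <- make_table(list(c(0, 0, 2, 2)))
  cs <- couple_set(c("s01", "s03"), c("s02", "s04"))
  expect_equal(compute_qm(tab, cs)$qm, 0.5)

  # all-heterozygote SNP: every pair scores 0.5
  tab2 <- make_table(list(rep(1, 4)))
  expect_equal(compute_qm(tab2, make_couples(tab2))$qm, 0.5)

  # random fixture incl. missing data vs brute force
  set.seed(14)
  d <- matrix(sample(c(0:2, NA), 20 * 10, TRUE, prob = c(.3, .3, .3, .1)),
              20, 10)
  tab3 <- make_table(lapply(seq_len(10), function(j) d[, j]))
  cs3 <- make_couples(tab3)
  got <- compute_qm(tab3, cs3)$per_snp
  gm <- tab3$dosages[tab3$sex == "male", ]
  gf <- tab3$dosages[tab3$sex == "female", ]
  bf <- vapply(seq_len(10), function(s) {
    mean(outer(gm[, s], gf[, s], identity_proportion), na.rm = TRUE)
  }, numeric(1))
  expect_equal(unname(got), bf, tolerance = 1e-12)

  # monomorphic identical-homozygote SNP flagged with Qm = 1
  mono <- compute_qm(make_table(list(rep(0, 4))),
                     make_couples(make_table(list(rep(0, 4)))))
  expect_true(mono$monomorphic[1])
  expect_equal(mono$qm, 1)
})

test_that("R1 is the null-centred ratio (Qc - Qm)/(1 - Qm)", {
  # identical spouses at polymorphic SNPs -> Qc = 1 -> R1 = 1
  tab <- make_table(list(c(0, 0, 2, 2), c(2, 2, 0, 0)))
  cs <- make_couples(tab)
  r1 <- compute_r1(tab, cs)
  expect_equal(r1$qc, 1)
  expect_equal(r1$r1, 1)

  # arithmetic: Qc = 0.75, Qm = 0.5 -> R1 = 0.5
  expect_equal((0.75 - 0.5) / (1 - 0.5), 0.5)
  # null centring: shuffled couples on a null sim give R1 near 0
  sim <- null_couple_sim(n = 500, m = 200, seed = 51)
  r1n <- compute_r1(sim$table, sim$couples)
  expect_lt(abs(r1n$r1), 0.01)
  # Qm = 1 -> undefined
  mono <- make_table(list(rep(2, 4)))
  expect_error(compute_r1(mono, make_couples(mono)), "undefined")
})

test_that("R1 is invariant under swapping the members of every couple", {
  sim <- null_couple_sim(n = 60, m = 40, seed = 52)
  swapped <- couple_set(sim$couples$female, sim$couples$male)
  tab <- sim$table
  tab$sex[] <- rep(c("female", "male"), each = 60)  # relabel to keep QC sane
  expect_equal(compute_r1(sim$table, sim$couples)$r1,
               compute_r1(tab, swapped)$r1)
})

test_that("spouse-permutation test behaves at the extremes", {
  # spouses genotypically identical, everyone else random: p = 0
  set.seed(53)
  gm <- matrix(rbinom(30 * 80, 2, 0.4), 30, 80)
  d <- matrix(NA_real_, 60, 80)
  d[seq(1, 60, 2), ] <- gm
  d[seq(2, 60, 2), ] <- gm
  tab <- make_table(lapply(seq_len(80), function(j) d[, j]))
  cs <- make_couples(tab)
  res <- permutation_test_r1(tab, cs, n_perm = 200, seed = 54)
  expect_equal(res$p_two_sided, 0)
  expect_equal(res$p_corrected, 1 / 201)

  # the identity permutation reproduces the observed R1 exactly
  ik <- identity_kernel(tab, cs)
  qm <- compute_qm(tab, cs)$qm
  expect_equal((mean(diag(ik$K)) - qm) / (1 - qm), res$r1)
})

test_that("kernel permutation statistics match direct recomputation", {
  sim <- null_couple_sim(n = 40, m = 30, seed = 55)
  ik <- identity_kernel(sim$table, sim$couples)
  qm <- compute_qm(sim$table, sim$couples)$qm
  set.seed(99)
  pi <- sample.int(40)
  reord <- couple_set(sim$couples$male, sim$couples$female[pi])
  direct <- compute_r1(sim$table, reord)
  kernel_r1 <- (mean(ik$K[cbind(1:40, pi)]) - qm) / (1 - qm)
  expect_equal(kernel_r1, direct$r1, tolerance = 1e-12)
})

test_that("R2 equals textbook Pearson correlation on dosages", {
  tab <- make_table(list(c(0, 1, 0, 0, 1, 2, 2, 2)))
  cs <- make_couples(tab)  # fathers c(0,0,1,2), mothers c(1,0,2,2)
  r2 <- compute_r2(tab, cs)
  expect_equal(r2$r2, cor(c(0, 0, 1, 2), c(1, 0, 2, 2)))
  expect_equal(r2$n_used, 4)

  perfect <- make_table(list(c(0, 0, 1, 1, 2, 2)))
  expect_equal(compute_r2(perfect, make_couples(perfect))$r2, 1)
  anti <- make_table(list(c(0, 2, 1, 1, 2, 0)))
  expect_equal(compute_r2(anti, make_couples(anti))$r2, -1)

  # zero variance flagged as NA
  flat <- make_table(list(c(1, 0, 1, 1, 1, 2)))  # fathers all 1
  expect_true(is.na(compute_r2(flat, make_couples(flat))$r2))
})

test_that("R2 is invariant under allele relabeling of both spouses", {
  sim <- null_couple_sim(n = 50, m = 20, seed = 56)
  flipped <- sim$table
  flipped$dosages <- 2 - flipped$dosages
  expect_equal(compute_r2(sim$table, sim$couples)$r2,
               compute_r2(flipped, sim$couples)$r2)
})

test_that("t-approximation p values match the t distribution tail", {
  r2res <- structure(
    data.frame(snp = c("a", "b"), r2 = c(0, 0.113), n_used = c(100, 930)),
    class = c("r2_result", "data.frame"))
  out <- snp_p_values(r2res, "t_approx")
  expect_equal(out$p_two[1], 1)
  expect_equal(out$p_two[2], 5.5e-4, tolerance = 0.01)
})

test_that("genome-background p values use the empirical R2 distribution", {
  sim <- null_couple_sim(n = 200, m = 500, seed = 57)
  r2res <- compute_r2(sim$table, sim$couples)
  out <- snp_p_values(r2res, "genome_background")
  z <- (r2res$r2 - mean(r2res$r2)) / sd(r2res$r2)
  expect_equal(out$p_two, pmin(1, 2 * pnorm(-abs(z))), tolerance = 1e-10)
  # robust variant runs and stays in [0, 1]
  outr <- snp_p_values(r2res, "genome_background", robust = TRUE)
  expect_true(all(outr$p_two >= 0 & outr$p_two <= 1))
})

test_that("perm_normal fits per-SNP null moments from reshuffles", {
  sim <- null_couple_sim(n = 150, m = 40, seed = 58)
  out <- snp_p_values(compute_r2(sim$table, sim$couples), "perm_normal",
                      table = sim$table, couples = sim$couples,
                      n_perm = 200, seed = 59)
  expect_true(all(out$p_two >= 0 & out$p_two <= 1))
  # null data: p values roughly uniform, not clustered at 0
  expect_gt(mean(out$p_two > 0.1), 0.6)
  expect_error(snp_p_values(compute_r2(sim$table, sim$couples),
                            "perm_normal", table = sim$table,
                            couples = sim$couples, n_perm = 0), "n_perm")
})

test_that("BH adjustment matches the hand step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  manual <- rev(cummin(rev(p * 5 / seq_len(5))))
  expect_equal(bh_fdr(p), pmin(1, manual))
})

test_that("sliding windows tile chromosomes as specified", {
  # 4.0 Mb chromosome, SNP every 10 kb: 5 windows of 3.6 Mb at 100 kb steps
  pos <- seq(1e4, 4e6, by = 1e4)
  map <- variant_map(paste0("s", seq_along(pos)), "chr1", pos)
  w <- sliding_windows(map, min_snps = 300)
  expect_equal(nrow(w), 5)
  expect_equal(w$start, seq(0, 4e5, by = 1e5))
  expect_true(all(w$n_snps >= 300))

  # chromosome shorter than the window: none
  short <- variant_map("a", "chr2", 5e5)
  expect_equal(nrow(sliding_windows(short)), 0)

  # min_snps = 0 retains every window
  w0 <- sliding_windows(map, min_snps = 0)
  expect_equal(nrow(w0), 5)

  # windows never span chromosomes
  map2 <- variant_map(paste0("t", seq_along(pos)),
                      rep(c("chr1", "chr2"), each = length(pos) / 2),
                      c(pos[1:200], pos[1:200]))
  w2 <- sliding_windows(map2, width_bp = 1e6, step_bp = 1e5, min_snps = 1)
  expect_gt(nrow(w2), 10)
  expect_true(all(w2$end - w2$start + 1 == 1e6))
  for (i in seq_len(nrow(w2))) {
    expect_equal(length(unique(map2$chrom[w2$snps[[i]]])), 1)
  }
})

test_that("centromere masking drops overlapping windows", {
  pos <- seq(1e4, 4e6, by = 1e4)
  cen <- pos > 1.9e6 & pos < 2.1e6
  map <- variant_map(paste0("s", seq_along(pos)), "chr1", pos,
                     centromere = cen)
  w <- sliding_windows(map, min_snps = 1, mask_centromere = TRUE)
  expect_equal(nrow(w), 0)  # every 3.6 Mb window covers the centromere
  wn <- sliding_windows(map, width_bp = 1e6, step_bp = 1e5, min_snps = 1,
                        mask_centromere = TRUE)
  expect_true(all(wn$end < 1.91e6 | wn$start > 2.09e6))
})

test_that("subset comparison brackets the reference correctly", {
  sim <- null_couple_sim(n = 100, m = 100, seed = 61)
  lo <- subset_r1_comparison(sim$table, sim$couples, k = 10, n_draws = 200,
                             reference_r1 = -Inf, seed = 62)
  hi <- subset_r1_comparison(sim$table, sim$couples, k = 10, n_draws = 200,
                             reference_r1 = Inf, seed = 62)
  expect_equal(lo$fraction_below, 0)
  expect_equal(hi$fraction_below, 1)

  full <- compute_r1(sim$table, sim$couples)$r1
  mid <- subset_r1_comparison(sim$table, sim$couples, k = 28, n_draws = 2000,
                              reference_r1 = full, seed = 63)
  expect_equal(mid$fraction_below, 0.5, tolerance = 0.06)
  expect_error(subset_r1_comparison(sim$table, sim$couples, k = 101,
                                    n_draws = 10, reference_r1 = 0),
               "exceeds")
})

test_that("LD pruning retains one tag per correlated block", {
  set.seed(64)
  base <- rbinom(100, 2, 0.4)
  noisy <- function(x) ifelse(runif(100) < 0.05, rbinom(100, 2, 0.4), x)
  tab <- make_table(list(base, base, noisy(base),
                         rbinom(100, 2, 0.4), rbinom(100, 2, 0.4)))
  kept <- ld_prune(tab, r2_threshold = 0.75, window_snps = 10)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)        # duplicate column dropped
  expect_false(3 %in% kept)        # r2 ~ 0.9 with SNP 1 dropped
  expect_true(all(c(4, 5) %in% kept))

  # independent SNPs all retained
  tab2 <- make_table(lapply(1:6, function(i) rbinom(200, 2, 0.3)))
  expect_equal(ld_prune(tab2, 0.25, 10), 1:6)
})
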