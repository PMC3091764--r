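test_that("Fisher combination matches the chi-square tail oracle", {
  fc <- fisher_combine(c(0.024, 0.024))
  expect_equal(fc$statistic, -2 * log(0.024) * 2, tolerance = 1e-12)
  expect_equal(fc$combined_p, pchisq(fc$statistic, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(fc$combined_p, 0.005)

  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1))$combined_p, 1)
  expect_equal(fisher_combine(0.5)$combined_p, 0.5)

  set.seed(71)
  for (k in c(1, 3, 10)) {
    p <- runif(k)
    fc <- fisher_combine(p)
    expect_equal(fc$combined_p,
                 pchisq(-2 * sum(log(p)), 2 * k, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_warning(fisher_combine(c(0, 0.5)), "clamped")
})

# shared fixture: assorted candidate region on its own chromosome plus
# null chromosomes that provide the matched background
meta_fixture <- function(rho = 0.25, n = 400, seed = 72) {
  spec <- simulation_spec(
    n, c(cand = 1e6, bgA = 3e6, bgB = 3e6, bgC = 3e6),
    snp_density = 100, maf_spec = 0.3,
    assortment = if (rho != 0)
      data.frame(chrom = "cand", start = 1, end = 5e5, rho = rho) else NULL,
    seed = seed)
  sim <- simulate_couples(spec)
  sim$r2res <- snp_p_values(compute_r2(sim$table, sim$couples), "t_approx")
  sim$cand <- region_window(sim$map, "cand", 1, 5e5)
  sim
}

test_that("sign modes partition the non-zero-R2 SNPs of a region", {
  fx <- meta_fixture(rho = 0, n = 120)
  sim_rows <- matescan:::meta_member_rows(fx$cand, fx$r2res, fx$map, "similar")
  dis_rows <- matescan:::meta_member_rows(fx$cand, fx$r2res, fx$map,
                                          "dissimilar")
  all_rows <- matescan:::meta_member_rows(fx$cand, fx$r2res, fx$map,
                                          "combined")
  expect_length(intersect(sim_rows, dis_rows), 0)
  expect_setequal(c(sim_rows, dis_rows), all_rows)
})

test_that("a region whose SNPs all have p = 1 gets meta value 1", {
  fx <- meta_fixture(rho = 0, n = 120)
  r2res <- fx$r2res
  r2res$p_one <- rep(1, nrow(r2res))
  m <- regional_meta(fx$cand, r2res, fx$map, "combined")
  expect_equal(m$meta_value, 1)
})

test_that("an assortative region yields an extreme similarity meta value", {
  fx <- meta_fixture(rho = 0.25, n = 400)
  m <- regional_meta(fx$cand, fx$r2res, fx$map, "similar")
  expect_lt(m$meta_value, 1e-3)
  expect_gt(m$n_snps_used, 25)
})

test_that("genome-matched backgrounds respect chromosome and recombination rules", {
  fx <- meta_fixture(rho = 0.25, n = 200)
  # vary recombination rates: candidate low, backgrounds mixed
  map <- fx$map
  # candidate low at 0.7; background rates sweep 0.2..3 along each
  # chromosome so matched windows exist on both sides
  map$cM_per_Mb <- ifelse(map$chrom == "cand", 0.7,
                          0.2 + 2.8 * map$pos / 3e6)
  expect_warning(
    bg <- build_background(map, region_window(map, "cand", 1, 5e5),
                           "genome_matched", r2res = fx$r2res,
                           sign_mode = "similar", step_bp = 1e5),
    "unstable")
  expect_false("cand" %in% bg$windows$chrom)
  cand_rate <- region_window(map, "cand", 1, 5e5)$mean_recomb
  expect_lte(cand_rate, bg$genome_avg_recomb)
  expect_true(all(bg$windows$mean_recomb <= cand_rate))
  expect_gt(length(bg$metas), 5)
})

test_that("empirical regional p counts smaller backgrounds", {
  bgv <- c(0.01, 0.2, 0.3, 0.35, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  ep <- empirical_region_p(0.33, bgv)
  expect_equal(ep$p, sum(bgv < 0.33) / 10)
  expect_equal(ep$background_mean, mean(bgv))
  expect_equal(empirical_region_p(0.005, bgv)$p, 0)
  expect_equal(empirical_region_p(0.95, bgv)$p, 1)
  expect_equal(ep$p_corrected, (3 + 1) / (10 + 1))
})

test_that("assorted candidate beats its genome background; flanks do not", {
  fx <- meta_fixture(rho = 0.3, n = 500, seed = 74)
  m <- regional_meta(fx$cand, fx$r2res, fx$map, "similar")
  bg <- build_background(fx$map, fx$cand, "genome_matched", r2res = fx$r2res,
                         sign_mode = "similar")
  expect_lt(empirical_region_p(m$meta_value, bg$metas)$p, 0.05)

  # a null window on a background chromosome is unremarkable
  null_w <- region_window(fx$map, "bgA", 1, 5e5)
  mn <- regional_meta(null_w, fx$r2res, fx$map, "similar")
  bgn <- build_background(fx$map, null_w, "genome_matched", r2res = fx$r2res,
                          sign_mode = "similar")
  expect_gt(empirical_region_p(mn$meta_value, bgn$metas)$p, 0.05)
})

test_that("permutation background recovers the candidate's signal", {
  fx <- meta_fixture(rho = 0.3, n = 300, seed = 75)
  m <- regional_meta(fx$cand, fx$r2res, fx$map, "similar")
  suppressWarnings(
    bg <- build_background(fx$map, fx$cand, "permutation", table = fx$table,
                           couples = fx$couples, sign_mode = "similar",
                           n_perm = 49, seed = 76))
  ep <- empirical_region_p(m$meta_value, bg$metas)
  expect_equal(ep$p, 0)
})

test_that("region scan returns matched-background p values and BH q", {
  fx <- meta_fixture(rho = 0.3, n = 300, seed = 77)
  scan <- region_scan(fx$table, fx$couples, fx$map, r2res = fx$r2res,
                      sign_mode = "similar", width_bp = 5e5, step_bp = 1e5,
                      min_snps = 30)
  expect_true(all(scan$empirical_p >= 0 & scan$empirical_p <= 1,
                  na.rm = TRUE))
  hit <- scan[scan$chrom == "cand" & scan$start == 0, ]
  expect_lt(hit$empirical_p, 0.05)
  expect_true(all(scan$q >= scan$empirical_p_corrected, na.rm = TRUE))
})
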