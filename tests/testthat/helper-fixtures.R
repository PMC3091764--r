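# In-code fixtures shared across test files.

# Small genotype table: dosage matrix built column-wise from a list of
# per-SNP vectors; samples alternate male/female.
make_table <- function(dosage_cols, chrom = "chr1",
                       pos = NULL, cM_per_Mb = 1, sex = NULL) {
  d <- do.call(cbind, dosage_cols)
  n <- nrow(d)
  rownames(d) <- sprintf("s%02d", seq_len(n))
  ids <- paste0("v", seq_len(ncol(d)))
  colnames(d) <- ids
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 1000
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  genotype_table(d, sex, variant_map(ids, chrom, pos, cM_per_Mb = cM_per_Mb))
}

# couples pairing odd rows (males) with even rows (females)
make_couples <- function(table) {
  ids <- rownames(table$dosages)
  couple_set(ids[table$sex == "male"], ids[table$sex == "female"])
}

# write a tiny PED/MAP pair; genos is a list per sample of allele strings
# like c("A A", "G G", ...)
write_ped_fixture <- function(dir, genos, sex_codes, map_rows) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  lines <- vapply(seq_along(genos), function(i) {
    paste(c("fam", paste0("ind", i), "0", "0", sex_codes[i], "-9",
            genos[[i]]), collapse = " ")
  }, character(1))
  writeLines(lines, ped)
  writeLines(vapply(map_rows, paste, character(1), collapse = " "), map)
  ped
}

# null couple world used by several calibration tests
null_couple_sim <- function(n = 100, m = 200, maf = 0.3, seed = 1) {
  spec <- simulation_spec(n, chromosomes = c(chr1 = m / 100 * 1e6),
                          snp_density = 100, maf_spec = maf, seed = seed)
  simulate_couples(spec)
}
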