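#' Read couple genotypes from disk
#'
#' Supports two plain-text layouts: PLINK-style `.ped`/`.map` pairs and a
#' samples x variants dosage matrix TSV. Dosages are coded as copies of the
#' alternate allele; when reading a PED the alternate allele is set to the
#' minor allele observed in the file and recorded in the returned variant map
#' (columns `a1`/`a2`), so the coding is reproducible. Unparseable genotype
#' calls (including PLINK's `0 0`) become missing.
#'
#' @param path for `ped_map`: path to the `.ped` file (the `.map` file is the
#'   same path with extension swapped) or the common prefix; for
#'   `matrix_tsv`: path to the dosage TSV.
#' @param format `"ped_map"` or `"matrix_tsv"`.
#' @param map a `variant_map` or path to a variant-map TSV; required for
#'   `matrix_tsv`, ignored for `ped_map` (positions come from the `.map`).
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("matrix_tsv", "ped_map"),
                           map = NULL) {
  format <- match.arg(format)
  if (format == "ped_map") read_ped_map(path) else read_matrix_tsv(path, map)
}

read_ped_map <- function(path) {
  ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[!grepl("^#", map_lines) & nzchar(trimws(map_lines))]
  mf <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(mf)
  if (any(nf < 4)) {
    stop("malformed MAP line ", which(nf < 4)[1], ": expected 4 fields")
  }
  mm <- do.call(rbind, mf)
  m <- nrow(mm)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  sex <- character(n)
  # allele calls as a n x 2m character matrix
  calls <- matrix(NA_character_, n, 2 * m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      stop("malformed PED line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(f))
    }
    ids[i] <- f[2]
    sex[i] <- switch(f[5], "1" = "male", "2" = "female", NA_character_)
    calls[i, ] <- f[-(1:6)]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample ID in PED: ", ids[anyDuplicated(ids)])
  }

  dos <- matrix(NA_real_, n, m, dimnames = list(ids, mm[, 2]))
  a1 <- character(m)
  a2 <- character(m)
  for (s in seq_len(m)) {
    al1 <- calls[, 2 * s - 1]
    al2 <- calls[, 2 * s]
    al1[al1 == "0"] <- NA
    al2[al2 == "0"] <- NA
    ok <- !is.na(al1) & !is.na(al2)
    alleles <- sort(unique(c(al1[ok], al2[ok])))
    if (length(alleles) > 2) {
      stop("more than two alleles at MAP variant ", mm[s, 2])
    }
    if (length(alleles) == 0) {
      a1[s] <- "?"; a2[s] <- "?"
      next
    }
    cnt <- table(factor(c(al1[ok], al2[ok]), levels = alleles))
    # alternate allele := minor allele (ties broken by sort order)
    ord <- order(cnt, seq_along(cnt))
    minor <- alleles[ord[1]]
    major <- if (length(alleles) == 2) alleles[ord[2]] else alleles[1]
    if (length(alleles) == 1) minor <- alleles[1]
    a1[s] <- major
    a2[s] <- minor
    dos[ok, s] <- (al1[ok] == minor) + (al2[ok] == minor)
  }

  vm <- variant_map(id = mm[, 2], chrom = mm[, 1],
                    pos = as.numeric(mm[, 4]), a1 = a1, a2 = a2)
  genotype_table(dos, sex, vm)
}

read_matrix_tsv <- function(path, map) {
  if (is.null(map)) stop("matrix_tsv format needs a variant map")
  if (is.character(map)) map <- read_variant_map(map)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("sample_id", "sex") %in% names(df))) {
    stop("matrix TSV needs 'sample_id' and 'sex' columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ID in matrix TSV")
  snp_cols <- setdiff(names(df), c("sample_id", "sex"))
  dos <- as.matrix(df[snp_cols])
  storage.mode(dos) <- "double"
  rownames(dos) <- df$sample_id
  if (!identical(snp_cols, map$id)) {
    stop("matrix TSV variant columns disagree with the variant map")
  }
  genotype_table(dos, stats::setNames(df$sex, df$sample_id), map)
}

#' Write a genotype table as a dosage matrix TSV (+ variant-map TSV)
#'
#' Inverse of `read_genotypes(format = "matrix_tsv")`: `read(write(x))` is
#' bit-exact on dosages.
#'
#' @param table a `genotype_table`
#' @param path output TSV path for the dosage matrix.
#' @param map_path optional path for the companion variant-map TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path, map_path = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  df <- data.frame(sample_id = rownames(table$dosages),
                   sex = unname(table$sex),
                   table$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) write_variant_map(table$variants, map_path)
  invisible(path)
}

#' Apply the study's variant quality-control filters
#'
#' Retains autosomal SNPs whose minor allele frequency (over all samples in
#' the table) exceeds `maf_min` and whose missingness is at most
#' `max_missing_per_sex` separately in males and in females. Idempotent.
#'
#' @param table a `genotype_table`
#' @param couples a `couple_set`; all coupled samples must carry sex labels.
#' @param maf_min minimum (exclusive) minor allele frequency, default 0.05.
#' @param max_missing_per_sex maximum (inclusive) fraction of missing
#'   genotypes per sex, default 0.10.
#' @param autosomes_only drop non-autosomal chromosomes (X/Y/XY/MT and PLINK
#'   codes 23-26), default TRUE.
#' @return the filtered `genotype_table`; warns (not errors) if no variant
#'   survives.
#' @export
apply_qc <- function(table, couples, maf_min = 0.05,
                     max_missing_per_sex = 0.10, autosomes_only = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  idx <- couple_indices(table, couples)
  if (anyNA(table$sex[c(idx$male, idx$female)])) {
    stop("all coupled samples must have sex labels")
  }
  d <- table$dosages
  keep <- rep(TRUE, ncol(d))

  if (autosomes_only) {
    non_auto <- c("X", "Y", "XY", "MT", "M", "chrX", "chrY", "chrM",
                  "23", "24", "25", "26")
    keep <- keep & !(table$variants$chrom %in% non_auto)
  }

  f_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f_alt, 1 - f_alt)
  maf[is.nan(maf)] <- 0          # fully missing column
  keep <- keep & maf > maf_min

  males <- table$sex == "male" & !is.na(table$sex)
  females <- table$sex == "female" & !is.na(table$sex)
  miss_m <- colMeans(is.na(d[males, , drop = FALSE]))
  miss_f <- colMeans(is.na(d[females, , drop = FALSE]))
  keep <- keep & miss_m <= max_missing_per_sex & miss_f <= max_missing_per_sex

  if (!any(keep)) warning("no variants pass QC")
  subset_genotypes(table, snps = which(keep))
}

#' Read a couples manifest
#'
#' Tab-separated with header columns `male_id` and `female_id` (or `male` /
#' `female`).
#'
#' @param path TSV path
#' @param table optional `genotype_table`; if given, every ID must resolve.
#' @return a [couple_set()]
#' @export
read_couples <- function(path, table = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  mcol <- intersect(c("male_id", "male"), names(df))[1]
  fcol <- intersect(c("female_id", "female"), names(df))[1]
  if (is.na(mcol) || is.na(fcol)) {
    stop("couples TSV needs male_id and female_id columns")
  }
  cs <- couple_set(df[[mcol]], df[[fcol]])
  if (!is.null(table)) couple_indices(table, cs)  # errors on unknown IDs
  cs
}

#' Read / write a variant-map TSV
#'
#' Columns: `id`, `chrom`, `pos`, `a1`, `a2`, `cM_per_Mb`,
#' `centromere_flag` (0/1). Lines starting `#` (e.g. a genome-build header)
#' are skipped.
#'
#' @param path TSV path
#' @return a [variant_map()]
#' @export
read_variant_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  variant_map(df$id, df$chrom, df$pos,
              a1 = if (is.null(df$a1)) "A" else df$a1,
              a2 = if (is.null(df$a2)) "B" else df$a2,
              cM_per_Mb = if (is.null(df$cM_per_Mb)) 1 else df$cM_per_Mb,
              centromere = if (is.null(df$centromere_flag)) FALSE
                           else df$centromere_flag != 0)
}

#' @rdname read_variant_map
#' @param map a `variant_map`
#' @export
write_variant_map <- function(map, path) {
  df <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                   a1 = map$a1, a2 = map$a2, cM_per_Mb = map$cM_per_Mb,
                   centromere_flag = as.integer(map$centromere))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an HLA typing TSV
#'
#' Columns `sample`, `gene`, `allele1`, `allele2`; alleles are two-digit
#' resolution strings and the pair is unordered.
#'
#' @param path TSV path
#' @return an [hla_table()]
#' @export
read_hla <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  hla_table(df$sample, df$gene, df$allele1, df$allele2)
}

#' Read a BED-like region file
#'
#' Columns `chrom`, `start`, `end`, `name`; intervals are 1-based closed
#' (`[start, end]`), matching printed Mbp region bounds.
#'
#' @param path TSV path
#' @return data frame with those columns.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("region file needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$name)) df$name <- paste0("region_", seq_len(nrow(df)))
  df[c("chrom", "start", "end", "name")]
}

#' Write analysis results with a run-metadata sidecar
#'
#' Each element of `results` (a data frame) is written as
#' `<dir>/<prefix>_<name>.tsv` with stable column order; a JSON sidecar
#' `<prefix>_meta.json` records the seed, parameters and package version.
#'
#' @param results named list of data frames
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @param seed integer seed used for the run (or NULL)
#' @param params list of run parameters for the sidecar
#' @return character vector of written paths, invisibly.
#' @export
write_results <- function(results, dir, prefix = "matescan", seed = NULL,
                          params = list()) {
  stopifnot(is.list(results), length(results) == 0 || !is.null(names(results)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    utils::write.table(as.data.frame(results[[nm]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(seed = seed, params = params,
               version = as.character(utils::packageVersion("matescan")),
               written = format(Sys.time(), tz = "UTC"))
  mp <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, null = "null")
  invisible(c(paths, mp))
}
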