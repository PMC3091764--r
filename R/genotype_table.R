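#' Construct a genotype table
#'
#' The central container for all spousal-similarity statistics: a samples x
#' variants matrix of diploid dosages (0, 1, 2 copies of the designated
#' alternate allele, `NA` for missing) together with per-sample sex labels and
#' a variant map describing each SNP.
#'
#' @param dosages integer/numeric matrix, samples in rows, variants in
#'   columns; entries must be 0, 1, 2 or `NA`. Row names are sample IDs,
#'   column names variant IDs.
#' @param sex character vector of `"male"`/`"female"`, one per sample (named
#'   by sample ID or in row order).
#' @param variants a `variant_map` (or data frame coercible to one) with one
#'   row per column of `dosages`, in the same order.
#' @return An object of class `genotype_table` with elements `dosages`,
#'   `sex`, `variants`.
#' @export
genotype_table <- function(dosages, sex, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages))) {
    stop("dosage matrix must have sample IDs as row names")
  }
  if (anyDuplicated(rownames(dosages))) {
    stop("duplicate sample IDs in genotype table")
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad]), collapse = ", "))
  }
  if (!is.null(names(sex))) sex <- sex[rownames(dosages)]
  sex <- as.character(sex)
  if (length(sex) != nrow(dosages)) {
    stop("need one sex label per sample")
  }
  if (!all(sex %in% c("male", "female", NA_character_))) {
    stop("sex labels must be 'male' or 'female'")
  }
  names(sex) <- rownames(dosages)
  variants <- as_variant_map(variants)
  if (nrow(variants) != ncol(dosages)) {
    stop("variant map rows (", nrow(variants), ") must match dosage columns (",
         ncol(dosages), ")")
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$id
  if (ncol(dosages) > 0 && !identical(colnames(dosages), variants$id)) {
    stop("dosage column names disagree with variant map IDs")
  }
  structure(list(dosages = dosages, sex = sex, variants = variants),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants\n")
  cat("  sex:", sum(x$sex == "male", na.rm = TRUE), "male,",
      sum(x$sex == "female", na.rm = TRUE), "female\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

#' Subset a genotype table by samples and/or variants
#'
#' @param table a `genotype_table`
#' @param samples sample IDs or indices (default: all)
#' @param snps variant IDs or indices (default: all)
#' @return a `genotype_table` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(table, samples = NULL, snps = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  d <- table$dosages
  v <- table$variants
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, v$id)
    if (anyNA(snps)) stop("unknown variant IDs in subset")
    d <- d[, snps, drop = FALSE]
    v <- v[snps, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(d))
    if (anyNA(samples)) stop("unknown sample IDs in subset")
    d <- d[samples, , drop = FALSE]
  }
  genotype_table(d, table$sex[rownames(d)], v)
}

#' Construct a couple set
#'
#' An ordered pairing of male and female sample IDs. The pairing defines the
#' couple-level statistics (Qc, per-SNP spousal correlation) and the unit that
#' permutation tests reshuffle.
#'
#' @param male,female character vectors of equal length; `male[i]` and
#'   `female[i]` are spouses.
#' @return An object of class `couple_set`: a data frame with columns
#'   `male`, `female`.
#' @export
couple_set <- function(male, female) {
  male <- as.character(male)
  female <- as.character(female)
  if (length(male) != length(female)) {
    stop("male and female ID vectors must have equal length")
  }
  if (anyDuplicated(c(male, female))) {
    stop("each sample may appear in at most one couple")
  }
  structure(data.frame(male = male, female = female,
                       stringsAsFactors = FALSE),
            class = c("couple_set", "data.frame"))
}

#' @export
print.couple_set <- function(x, ...) {
  cat("couple_set:", nrow(x), "couples\n")
  invisible(x)
}

# Check every couple ID resolves in the table; returns row indices of the
# male and female member of each couple.
couple_indices <- function(table, couples) {
  ids <- rownames(table$dosages)
  im <- match(couples$male, ids)
  iff <- match(couples$female, ids)
  if (anyNA(im) || anyNA(iff)) {
    missing <- c(couples$male[is.na(im)], couples$female[is.na(iff)])
    stop("couple sample IDs absent from genotype table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  list(male = im, female = iff)
}

#' Construct a variant map
#'
#' Per-SNP metadata: identifier, chromosome, 1-based base-pair position,
#' allele labels (a1 = reference/major, a2 = alternate/minor as coded in the
#' dosages), local recombination rate in cM/Mb, and a centromere flag used to
#' mask windows from background tiling.
#'
#' @param id,chrom,pos,a1,a2 per-variant identifier, chromosome label,
#'   position (bp, 1-based), allele labels.
#' @param cM_per_Mb recombination rate, non-negative (default 1).
#' @param centromere logical flag (default `FALSE`).
#' @return data frame of class `variant_map`, sorted check enforced:
#'   positions strictly increasing within each chromosome.
#' @export
variant_map <- function(id, chrom, pos, a1 = "A", a2 = "B",
                        cM_per_Mb = 1, centromere = FALSE) {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   pos = as.numeric(pos), a1 = as.character(a1),
                   a2 = as.character(a2),
                   cM_per_Mb = as.numeric(cM_per_Mb),
                   centromere = as.logical(centromere),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate variant IDs")
  if (any(df$cM_per_Mb < 0, na.rm = TRUE)) {
    stop("recombination rates must be non-negative")
  }
  incr <- unlist(tapply(df$pos, factor(df$chrom, levels = unique(df$chrom)),
                        function(p) c(TRUE, diff(p) > 0)), use.names = FALSE)
  if (!all(incr)) {
    stop("positions must be strictly increasing within each chromosome")
  }
  class(df) <- c("variant_map", "data.frame")
  df
}

as_variant_map <- function(x) {
  if (inherits(x, "variant_map")) return(x)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(x))) {
    stop("variant map needs columns: ", paste(need, collapse = ", "))
  }
  variant_map(x$id, x$chrom, x$pos,
              a1 = if (is.null(x$a1)) "A" else x$a1,
              a2 = if (is.null(x$a2)) "B" else x$a2,
              cM_per_Mb = if (is.null(x$cM_per_Mb)) 1 else x$cM_per_Mb,
              centromere = if (is.null(x$centromere)) FALSE else x$centromere)
}

#' Construct an HLA typing table
#'
#' One row per (sample, gene) with an unordered pair of alleles at two-digit
#' resolution. Allele order within a row carries no meaning.
#'
#' @param sample,gene,allele1,allele2 character vectors of equal length.
#' @return data frame of class `hla_table`.
#' @export
hla_table <- function(sample, gene, allele1, allele2) {
  df <- data.frame(sample = as.character(sample), gene = as.character(gene),
                   allele1 = as.character(allele1),
                   allele2 = as.character(allele2),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("sample", "gene")])) {
    stop("duplicate (sample, gene) rows in HLA table")
  }
  class(df) <- c("hla_table", "data.frame")
  df
}
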