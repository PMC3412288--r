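#' Construct a genotype matrix object
#'
#' The central genotype container: an `N` subjects by `M` SNPs matrix of
#' additive minor-allele dosages together with per-SNP metadata. Dosages are
#' counts of the minor allele (0, 1 or 2); fractional values in `[0, 2]` are
#' permitted for imputed data.
#'
#' @param dosages Numeric matrix, subjects in rows, SNPs in columns, values in
#'   `[0, 2]`. Row names (subject ids) and column names (SNP ids) are required
#'   unless supplied through `snps`/`subject_ids`.
#' @param snps A data frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per SNP, in column order of `dosages`. Optional; a
#'   placeholder is built from column names when absent.
#' @param subject_ids Character vector of subject ids; defaults to
#'   `rownames(dosages)`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (named numeric matrix) and `snps` (tibble of SNP metadata).
#' @export
genotype_matrix <- function(dosages, snps = NULL, subject_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.null(subject_ids)) rownames(dosages) <- subject_ids
  if (is.null(rownames(dosages))) {
    abort("subject ids are required (rownames of `dosages` or `subject_ids`)")
  }
  if (is.null(snps)) {
    if (is.null(colnames(dosages))) {
      abort("SNP ids are required (colnames of `dosages` or `snps$snp_id`)")
    }
    snps <- tibble::tibble(
      snp_id = colnames(dosages), chrom = NA_character_,
      pos = NA_integer_, ref = NA_character_, alt = NA_character_
    )
  } else {
    snps <- tibble::as_tibble(snps)
    need <- c("snp_id", "chrom", "pos", "ref", "alt")
    missing_cols <- setdiff(need, names(snps))
    if (length(missing_cols) > 0) {
      abort(paste0("`snps` lacks columns: ", paste(missing_cols, collapse = ", ")))
    }
    colnames(dosages) <- snps$snp_id
  }
  if (nrow(snps) != ncol(dosages)) abort("`snps` must have one row per dosage column")
  if (anyDuplicated(snps$snp_id)) abort("SNP ids must be unique")
  if (anyDuplicated(rownames(dosages))) abort("subject ids must be unique")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    abort("dosages must lie in [0, 2]")
  }
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d subjects x %d SNPs\n",
    nrow(x$dosages), ncol(x$dosages)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subject ids of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(g) rownames(g$dosages)

#' Subset a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @param subjects,snps Character ids (or integer/logical indices) of the rows
#'   and columns to keep, in the requested order. `NULL` keeps everything.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, subjects = NULL, snps = NULL) {
  d <- g$dosages
  meta <- g$snps
  if (!is.null(subjects)) d <- d[subjects, , drop = FALSE]
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    idx <- match(colnames(d), meta$snp_id)
    meta <- meta[idx, , drop = FALSE]
  }
  genotype_matrix(d, snps = meta)
}

# Per-SNP mean imputation of missing dosages; returns the matrix plus count.
impute_mean <- function(d) {
  n_missing <- sum(is.na(d))
  if (n_missing > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  list(dosages = d, n_imputed = n_missing)
}

# Flip columns whose coded-allele frequency exceeds 0.5 so that dosages count
# the MINOR allele. At frequency exactly 0.5 the alt allele stays minor.
recode_minor <- function(d, snps) {
  f <- colMeans(d) / 2
  flip <- f > 0.5
  if (any(flip)) {
    d[, flip] <- 2 - d[, flip, drop = FALSE]
    tmp <- snps$ref[flip]
    snps$ref[flip] <- snps$alt[flip]
    snps$alt[flip] <- tmp
  }
  list(dosages = d, snps = snps, n_flipped = sum(flip))
}

#' Read genotypes from VCF or a dosage table
#'
#' Reads a VCF (GT field, bi-allelic sites) or a rectangular tab-separated
#' dosage table into a [genotype_matrix()]. Dosages are recoded so that they
#' always count the minor allele; at an allele-frequency tie of exactly 0.5
#' the alt allele is treated as minor. Missing genotypes are mean-imputed per
#' SNP (the count is reported with a message). SNP order follows file order.
#'
#' The dosage table format has a header line
#' `snp_id chr pos ref alt <subject_1> <subject_2> ...` followed by one row
#' per SNP with additive dosages in `[0, 2]` (`NA` for missing); positions are
#' 1-based.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @param skip_multiallelic For VCF input: drop multi-allelic sites instead of
#'   erroring.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                           skip_multiallelic = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "vcf") read_genotypes_vcf(path, skip_multiallelic)
  else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path, skip_multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (!skip_multiallelic) {
      abort(paste0(
        "multi-allelic site(s) at record(s) ", paste(which(multi), collapse = ", "),
        "; set skip_multiallelic = TRUE to drop them"
      ))
    }
    inform(sprintf("dropped %d multi-allelic site(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0) abort("no bi-allelic sites retained")
  # count alt alleles in the GT string; "." contributes NA
  count_alt <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    v <- suppressWarnings(as.numeric(al))
    if (anyNA(v) || any(!v %in% c(0, 1))) {
      abort(paste0("malformed or non-bi-allelic genotype call: ", s))
    }
    sum(v)
  }
  d <- t(apply(gt, 1, function(row) vapply(row, count_alt, numeric(1))))
  if (ncol(gt) == 1) d <- matrix(d, ncol = 1, dimnames = list(rownames(gt), colnames(gt)))
  d <- t(d) # subjects x SNPs
  snp_id <- unname(fix[, "ID"])
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  snps <- tibble::tibble(
    snp_id = snp_id, chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]), ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"])
  )
  imp <- impute_mean(d)
  if (imp$n_imputed > 0) {
    inform(sprintf("mean-imputed %d missing genotype call(s)", imp$n_imputed))
  }
  rec <- recode_minor(imp$dosages, snps)
  if (rec$n_flipped > 0) {
    inform(sprintf("recoded %d SNP(s) to minor-allele dosage", rec$n_flipped))
  }
  genotype_matrix(rec$dosages, snps = rec$snps)
}

read_genotypes_dosage <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("snp_id", "chr", "pos", "ref", "alt")
  if (!all(need %in% names(tab)[seq_len(5)])) {
    abort("dosage table header must start with: snp_id chr pos ref alt")
  }
  subj <- names(tab)[-seq_len(5)]
  if (length(subj) == 0) abort("dosage table has no subject columns")
  d <- t(as.matrix(tab[, -seq_len(5)]))
  colnames(d) <- tab$snp_id
  rownames(d) <- subj
  storage.mode(d) <- "double"
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "dosage out of [0, 2] for SNP row ", bad[1, 2], " (line ", bad[1, 2] + 1,
      " of ", path, ")"
    ))
  }
  snps <- tibble::tibble(
    snp_id = tab$snp_id, chrom = as.character(tab$chr),
    pos = as.integer(tab$pos), ref = as.character(tab$ref),
    alt = as.character(tab$alt)
  )
  imp <- impute_mean(d)
  if (imp$n_imputed > 0) {
    inform(sprintf("mean-imputed %d missing dosage value(s)", imp$n_imputed))
  }
  rec <- recode_minor(imp$dosages, snps)
  if (rec$n_flipped > 0) {
    inform(sprintf("recoded %d SNP(s) to minor-allele dosage", rec$n_flipped))
  }
  genotype_matrix(rec$dosages, snps = rec$snps)
}

#' Write genotypes as a dosage table
#'
#' Inverse of [read_genotypes()] for the `dosage_tsv` format.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  tab <- tibble::tibble(
    snp_id = g$snps$snp_id, chr = g$snps$chrom, pos = g$snps$pos,
    ref = g$snps$ref, alt = g$snps$alt
  )
  dos <- tibble::as_tibble(t(g$dosages), .name_repair = "minimal")
  names(dos) <- rownames(g$dosages)
  readr::write_tsv(dplyr::bind_cols(tab, dos), path, progress = FALSE)
  invisible(path)
}

#' Read a SNP-to-gene assignment map
#'
#' Reads a two-column tab-separated file with header `snp_id<TAB>gene_id`,
#' one row per intragenic SNP. A SNP listed under several overlapping genes is
#' assigned to the lexicographically first gene id (with a warning), so each
#' SNP belongs to exactly one gene. Genes are ordered lexicographically.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `snp_id`, `gene_id`, class `gene_map`.
#' @export
read_gene_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("snp_id", "gene_id") %in% names(tab))) {
    abort("gene map must have columns snp_id and gene_id")
  }
  gene_map(tab)
}

#' Build a gene map from SNP/gene pairs
#'
#' @param pairs Data frame with columns `snp_id` and `gene_id`.
#' @return A tibble of class `gene_map` (columns `snp_id`, `gene_id`), genes
#'   in lexicographic order, each SNP assigned to exactly one gene.
#' @export
gene_map <- function(pairs) {
  tab <- tibble::as_tibble(pairs)[, c("snp_id", "gene_id")]
  tab <- dplyr::distinct(tab)
  if (nrow(tab) == 0) abort("gene map is empty")
  dup <- tab$snp_id[duplicated(tab$snp_id)]
  if (length(dup) > 0) {
    warn(sprintf(
      "%d SNP(s) mapped to multiple genes; keeping the lexicographically first gene for each",
      length(unique(dup))
    ))
    tab <- tab |>
      dplyr::arrange(.data$snp_id, .data$gene_id) |>
      dplyr::distinct(.data$snp_id, .keep_all = TRUE)
  }
  tab <- dplyr::arrange(tab, .data$gene_id, .data$snp_id)
  class(tab) <- c("gene_map", class(tab))
  tab
}

#' Write a gene map
#' @param map A `gene_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map)[, c("snp_id", "gene_id")], path,
    progress = FALSE
  )
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated, one row per subject, with a `subject_id` key column;
#' remaining columns are phenotypes and covariates.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(tab)) abort("phenotype table needs a subject_id column")
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) abort("duplicate subject_id in phenotype table")
  tab
}

#' Align genotypes and phenotypes on shared subjects
#'
#' Restricts both inputs to the intersection of their subject ids, drops
#' subjects with any missing phenotype or covariate value (reporting the
#' count), and puts both in the same deterministic (sorted) subject order, so
#' the result does not depend on the input row order.
#'
#' @param g A [genotype_matrix()].
#' @param phenotypes A tibble with a `subject_id` column (see
#'   [read_phenotypes()]).
#' @return A list of class `cohort` with elements `genotypes` and
#'   `phenotypes`, subject-aligned 1:1.
#' @export
join_cohort <- function(g, phenotypes) {
  phenotypes <- tibble::as_tibble(phenotypes)
  complete <- stats::complete.cases(phenotypes)
  if (any(!complete)) {
    inform(sprintf(
      "dropped %d subject(s) with missing phenotype/covariate values",
      sum(!complete)
    ))
    phenotypes <- phenotypes[complete, , drop = FALSE]
  }
  shared <- sort(intersect(subject_ids(g), phenotypes$subject_id))
  if (length(shared) == 0) abort("no shared subjects between genotypes and phenotypes")
  g2 <- subset_genotypes(g, subjects = shared)
  p2 <- phenotypes[match(shared, phenotypes$subject_id), , drop = FALSE]
  structure(list(genotypes = g2, phenotypes = p2), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects, %d SNPs, phenotype columns: %s\n",
    nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
    paste(setdiff(names(x$phenotypes), "subject_id"), collapse = ", ")
  ))
  invisible(x)
}
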