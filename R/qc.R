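#' Minor allele frequency of a dosage column
#'
#' The coded-allele frequency is `sum(dosage) / (2 N)`; the minor allele
#' frequency folds it to `[0, 0.5]`.
#'
#' @param dosage Numeric vector of additive dosages in `[0, 2]`.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(dosage) {
  if (length(dosage) == 0) abort("empty dosage column")
  if (anyNA(dosage) || any(dosage < 0 | dosage > 2)) {
    abort("dosages must be non-missing and in [0, 2]")
  }
  f <- sum(dosage) / (2 * length(dosage))
  min(f, 1 - f)
}

# Folded MAF for every column of a dosage matrix.
maf_by_snp <- function(d) {
  f <- colMeans(d) / 2
  pmin(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of Hardy-Weinberg genotype proportions, conditioning
#' on the observed allele counts and enumerating all heterozygote counts of
#' the compatible parity (the Wigginton/Levene formulation): the p-value is
#' the total probability of tables no more likely than the observed one.
#' Monomorphic SNPs return `p = 1`.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectors are recycled to a common
#'   length): major homozygotes, heterozygotes, minor homozygotes. The
#'   labelling is symmetric: swapping `n_AA` and `n_aa` leaves p unchanged.
#' @return Vector of exact p-values in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, n)
  n_Aa <- rep_len(n_Aa, n)
  n_aa <- rep_len(n_aa, n)
  vapply(seq_len(n), function(i) {
    hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  N <- sum(counts)
  if (N < 1) abort("at least one genotype is required")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_rare == 0 || n_rare == 2 * N) return(1)
  # log-probability of each heterozygote count given allele counts, via the
  # hypergeometric-style closed form; parity of het count is fixed by n_rare
  hets <- seq(n_rare %% 2, min(n_rare, 2 * N - n_rare), by = 2)
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- N - h - hom_r
    h * log(2) + lgamma(N + 1) -
      (lgamma(hom_r + 1) + lgamma(h + 1) + lgamma(hom_c + 1)) +
      lgamma(n_rare + 1) + lgamma(2 * N - n_rare + 1) - lgamma(2 * N + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Apply SNP-level quality control
#'
#' Retains SNPs with minor allele frequency strictly above `maf_threshold`
#' and exact Hardy-Weinberg p-value at or above `hwe_threshold` (i.e. SNPs
#' with HWE p below the threshold are excluded as likely genotyping
#' artifacts). The defaults are the common-variant GWAS filters
#' `maf > 0.1` and `hwe_p >= 5.7e-7`. Fractional (imputed) dosages are
#' hard-called to the nearest genotype for the HWE test only; downstream
#' modelling keeps the fractional values.
#'
#' @param g A [genotype_matrix()].
#' @param maf_threshold Exclude SNPs with MAF at or below this value.
#' @param hwe_threshold Exclude SNPs with exact HWE p-value below this value.
#' @return A list of class `qc_result`: `genotypes` (the filtered
#'   [genotype_matrix()]) and `report`, a tibble with one row per input SNP
#'   (`snp_id`, `maf`, `hwe_p`, `keep`, `reasons`).
#' @export
apply_qc <- function(g, maf_threshold = 0.1, hwe_threshold = 5.7e-7) {
  d <- g$dosages
  maf <- maf_by_snp(d)
  hard <- round(d)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- hard[, j]
    hwe_exact_one(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  low_maf <- maf <= maf_threshold
  hwe_fail <- hwe_p < hwe_threshold
  keep <- !low_maf & !hwe_fail
  reasons <- mapply(function(a, b) {
    paste(c(if (a) "low_maf", if (b) "hwe_fail"), collapse = ",")
  }, low_maf, hwe_fail)
  report <- tibble::tibble(
    snp_id = g$snps$snp_id, maf = unname(maf), hwe_p = hwe_p,
    keep = unname(keep), reasons = unname(reasons)
  )
  if (!any(keep)) {
    abort("all SNPs removed by QC; review maf_threshold / hwe_threshold")
  }
  structure(
    list(genotypes = subset_genotypes(g, snps = which(keep)), report = report),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> %d / %d SNPs retained\n",
    sum(x$report$keep), nrow(x$report)
  ))
  invisible(x)
}

#' @rdname apply_qc
#' @param x A `qc_result`.
#' @param ... Unused.
#' @export
tidy.qc_result <- function(x, ...) x$report

#' Write a QC report as TSV
#' @param qc A `qc_result` from [apply_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  readr::write_tsv(qc$report, path, progress = FALSE)
  invisible(path)
}
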