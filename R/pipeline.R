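# Line-oriented run log with ISO timestamps; NULL path = messages only.
log_line <- function(path, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", sprintf(...))
  if (!is.null(path)) cat(line, "\n", sep = "", file = path, append = TRUE)
  inform(sprintf(...))
  invisible(line)
}

#' Run the discovery gene-scan workflow from files
#'
#' End-to-end discovery pipeline: read genotypes, gene map and phenotypes;
#' align the cohort; apply MAF/HWE quality control; run the per-gene LASSO
#' selection plus joint partial F-tests; flag genes at the Bonferroni
#' threshold. Writes `<out_prefix>_genes.tsv`, `<out_prefix>_qc.tsv` and a
#' run log `<out_prefix>.log` when `out_prefix` is given.
#'
#' @param genotype_file VCF or dosage-table path (see [read_genotypes()]).
#' @param gene_map_file SNP-to-gene TSV (see [read_gene_map()]).
#' @param phenotype_file Phenotype/covariate TSV (see [read_phenotypes()]).
#' @param phenotype,covariates Column names in the phenotype table.
#' @param maf_threshold,hwe_threshold QC thresholds (see [apply_qc()]).
#' @param alpha,n_genes Bonferroni control (see [gene_scan()]).
#' @param n_pcs Number of ancestry principal components appended to the
#'   covariates (0 disables).
#' @param n_folds CV folds for the per-gene LASSO (`NULL` = leave-one-out).
#' @param seed Seed recorded in the log and used for any randomized steps.
#' @param out_prefix Output path prefix, or `NULL` to skip writing.
#' @return The `gene_scan` tibble, invisibly when writing.
#' @export
run_gene_scan <- function(genotype_file, gene_map_file, phenotype_file,
                          phenotype = "phenotype", covariates = NULL,
                          maf_threshold = 0.1, hwe_threshold = 5.7e-7,
                          alpha = 0.05, n_genes = NULL, n_pcs = 0,
                          n_folds = NULL, seed = 1, out_prefix = NULL) {
  log_path <- if (is.null(out_prefix)) NULL else paste0(out_prefix, ".log")
  if (!is.null(log_path) && file.exists(log_path)) file.remove(log_path)
  log_line(
    log_path, "gene-scan start (genefscan %s), seed=%d",
    as.character(utils::packageVersion("genefscan")), seed
  )
  g <- read_genotypes(genotype_file)
  map <- read_gene_map(gene_map_file)
  ph <- read_phenotypes(phenotype_file)
  unmapped <- sum(!g$snps$snp_id %in% map$snp_id)
  log_line(log_path, "inputs: %d subjects, %d SNPs (%d not in any gene), %d genes",
    nrow(g$dosages), ncol(g$dosages), unmapped, length(unique(map$gene_id))
  )
  cohort <- join_cohort(g, ph)
  qc <- apply_qc(cohort$genotypes,
    maf_threshold = maf_threshold, hwe_threshold = hwe_threshold
  )
  log_line(
    log_path, "QC (maf > %g, hwe_p >= %g): %d / %d SNPs retained",
    maf_threshold, hwe_threshold, sum(qc$report$keep), nrow(qc$report)
  )
  if (n_pcs > 0) {
    pcs <- genotype_pcs(qc$genotypes, k = n_pcs)
    cohort$phenotypes <- dplyr::inner_join(cohort$phenotypes, pcs, by = "subject_id")
    covariates <- c(covariates, setdiff(names(pcs), "subject_id"))
    log_line(log_path, "added %d ancestry PCs to covariates", n_pcs)
  }
  res <- gene_scan(qc$genotypes, map, cohort$phenotypes,
    phenotype = phenotype, covariates = covariates, alpha = alpha,
    n_genes = n_genes, n_folds = n_folds, seed = seed
  )
  log_line(
    log_path, "scan: %d genes tested, %d significant at p < %.3g",
    nrow(res), sum(res$significant), attr(res, "threshold")
  )
  if (!is.null(out_prefix)) {
    write_gene_scan(res, paste0(out_prefix, "_genes.tsv"))
    write_qc_report(qc, paste0(out_prefix, "_qc.tsv"))
    log_line(log_path, "wrote %s_genes.tsv and %s_qc.tsv", out_prefix, out_prefix)
    return(invisible(res))
  }
  res
}

#' Run the replication workflow with a fixed discovery SNP list
#'
#' Replication never re-selects SNPs: the discovery-selected SNP ids are
#' taken as given (`snp_list_file`, one id per line), intersected with the
#' replication genotypes (dropped ids are logged), and tested jointly. With
#' a kinship matrix the mixed-model partial F-test is used (related
#' samples); otherwise the ordinary partial F-test. When a voxel table is
#' supplied, a voxelwise F-map with Benjamini-Hochberg FDR control is
#' produced as well.
#'
#' @inheritParams run_gene_scan
#' @param snp_list_file Text file with one SNP id per line.
#' @param kinship_file Optional square kinship TSV (see [read_kinship()]).
#' @param voxel_file Optional subject-by-voxel TSV (first column
#'   `subject_id`).
#' @param q FDR level for the voxelwise map.
#' @return List: `scalar` (one-row test tibble), `voxelwise` (tibble or
#'   `NULL`), `fdr` (`fdr_result` or `NULL`), `snps_used`, `snps_dropped`.
#' @export
run_replicate <- function(genotype_file, phenotype_file, snp_list_file,
                          phenotype = "phenotype", covariates = NULL,
                          kinship_file = NULL, voxel_file = NULL, q = 0.05,
                          out_prefix = NULL) {
  log_path <- if (is.null(out_prefix)) NULL else paste0(out_prefix, ".log")
  if (!is.null(log_path) && file.exists(log_path)) file.remove(log_path)
  snp_list <- readr::read_lines(snp_list_file, progress = FALSE)
  snp_list <- snp_list[nzchar(snp_list)]
  if (length(snp_list) == 0) abort("empty SNP list")
  g <- read_genotypes(genotype_file)
  ph <- read_phenotypes(phenotype_file)
  cohort <- join_cohort(g, ph)
  present <- intersect(snp_list, colnames(cohort$genotypes$dosages))
  dropped <- setdiff(snp_list, present)
  if (length(dropped) > 0) {
    log_line(
      log_path, "%d of %d listed SNPs absent from replication genotypes; dropped",
      length(dropped), length(snp_list)
    )
  }
  if (length(present) == 0) abort("no listed SNPs present in the replication genotypes")
  S <- cohort$genotypes$dosages[, present, drop = FALSE]
  des <- extract_design(cohort$phenotypes, phenotype, covariates)
  K <- NULL
  if (!is.null(kinship_file)) {
    K <- read_kinship(kinship_file)
    ids <- cohort$phenotypes$subject_id
    if (!all(ids %in% rownames(K))) abort("kinship matrix does not cover the cohort")
    K <- K[ids, ids]
  }
  scalar <- if (is.null(K)) {
    partial_f_test(des$y, S, des$C)
  } else {
    mixed_partial_f_test(des$y, S, des$C, K)
  }
  log_line(
    log_path, "replication test: %d SNPs, F = %.3f (df %d, %d), p = %.3g",
    length(present), scalar$F, scalar$df1, scalar$df2, scalar$p
  )
  vox_res <- NULL
  fdr <- NULL
  if (!is.null(voxel_file)) {
    vox <- readr::read_tsv(voxel_file, show_col_types = FALSE, progress = FALSE)
    if (!"subject_id" %in% names(vox)) abort("voxel table needs a subject_id column")
    idx <- match(cohort$phenotypes$subject_id, vox$subject_id)
    if (anyNA(idx)) abort("voxel table does not cover the cohort")
    Y <- as.matrix(vox[idx, setdiff(names(vox), "subject_id"), drop = FALSE])
    vox_res <- voxelwise_f_map(Y, S, des$C, K = K)
    fdr <- bh_fdr(setNames(vox_res$p, vox_res$voxel_id), q = q)
    log_line(
      log_path, "voxelwise map: %d / %d voxels significant at FDR q = %g",
      fdr$n_significant, length(fdr$mask), q
    )
    if (!is.null(out_prefix)) {
      write_fdr_result(fdr, paste0(out_prefix, "_voxels.tsv"))
    }
  }
  if (!is.null(out_prefix)) {
    readr::write_tsv(scalar, paste0(out_prefix, "_scalar.tsv"), progress = FALSE)
  }
  list(
    scalar = scalar, voxelwise = vox_res, fdr = fdr,
    snps_used = present, snps_dropped = dropped
  )
}
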