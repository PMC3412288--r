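#' Voxelwise partial F-map for a fixed SNP set
#'
#' Repeats the partial F-test of one selected SNP block at every voxel
#' (column) of a subject-by-voxel phenotype matrix. The covariate and SNP
#' projections are computed once and reused across voxels, which is
#' numerically identical to looping [partial_f_test()] per column. With a
#' kinship matrix the mixed-model test is applied per voxel (variance
#' components re-estimated per voxel through a shared eigendecomposition).
#'
#' @param Y Numeric matrix, subjects in rows, voxels in columns (a data
#'   frame with an optional `subject_id` column is accepted). Column names
#'   become voxel ids.
#' @param S SNP dosage block (N x k).
#' @param C Covariate matrix without intercept, or `NULL`.
#' @param K Optional kinship matrix for related samples.
#' @return Tibble: `voxel_id`, `F`, `df1`, `df2`, `p`.
#' @export
voxelwise_f_map <- function(Y, S, C = NULL, K = NULL) {
  if (is.data.frame(Y)) {
    Y <- Y[, setdiff(names(Y), "subject_id"), drop = FALSE]
    Y <- as.matrix(Y)
  }
  storage.mode(Y) <- "double"
  if (anyNA(Y)) abort("voxel phenotypes must not contain missing values")
  V <- ncol(Y)
  if (V < 1) abort("at least one voxel column is required")
  voxel_id <- colnames(Y) %||% paste0("v", seq_len(V))
  N <- nrow(Y)
  S <- as.matrix(S)
  if (!is.null(K)) {
    prep <- NULL
    rows <- purrr::map(seq_len(V), function(v) {
      res <- mixed_partial_f_test(Y[, v], S, C, K, prep = prep)
      prep <<- attr(res, "prep")
      res[, c("F", "df1", "df2", "p")]
    })
    return(dplyr::bind_cols(
      tibble::tibble(voxel_id = voxel_id), dplyr::bind_rows(rows)
    ))
  }
  Cfull <- design_with_intercept(C, N)
  c_dim <- qr(Cfull)$rank
  qc <- qr.Q(qr(Cfull))[, seq_len(c_dim), drop = FALSE]
  S_perp <- S - qc %*% crossprod(qc, S)
  qrS <- qr(S_perp)
  scale_ref <- max(sqrt(colSums(S^2)), .Machine$double.eps)
  df1 <- sum(abs(diag(qrS$qr)[seq_len(min(dim(S_perp)))]) > 1e-8 * scale_ref)
  df2 <- N - c_dim - df1
  if (df1 == 0) {
    return(tibble::tibble(
      voxel_id = voxel_id, F = 0, df1 = 0L,
      df2 = as.integer(N - c_dim), p = 1
    ))
  }
  if (df2 <= 0) abort("not enough observations: N <= covariates + selected SNPs")
  qs <- qr.Q(qrS)[, seq_len(df1), drop = FALSE]
  Y_perp <- Y - qc %*% crossprod(qc, Y)
  rss_red <- colSums(Y_perp^2)
  fitted2 <- colSums(crossprod(qs, Y_perp)^2)
  rss_full <- pmax(rss_red - fitted2, 0)
  Fstat <- (fitted2 / df1) / (rss_full / df2)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  tibble::tibble(
    voxel_id = voxel_id, F = unname(Fstat), df1 = as.integer(df1),
    df2 = as.integer(df2), p = unname(p)
  )
}

#' Benjamini-Hochberg FDR control over a p-value map
#'
#' Step-up procedure at level `q`: with sorted p-values `p_(1) <= ... <=
#' p_(V)`, the adaptive threshold is `p_(i*)` for the largest `i*` with
#' `p_(i) <= i q / V`; no such `i` gives an empty significance mask.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`, optionally named by
#'   voxel id.
#' @param q Target false discovery rate.
#' @return List of class `fdr_result`: `q`, `p_threshold` (`0` when nothing
#'   passes), `mask` (logical, names preserved), `prop_significant`,
#'   `n_significant`, and the input `pvals`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) abort("empty p-value vector")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  V <- length(pvals)
  ord <- sort(pvals)
  pass <- which(ord <= seq_len(V) * q / V)
  p_threshold <- if (length(pass) == 0) 0 else ord[max(pass)]
  mask <- pvals <= p_threshold
  structure(list(
    q = q, p_threshold = p_threshold, mask = mask,
    prop_significant = mean(mask), n_significant = sum(mask),
    pvals = pvals
  ), class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf(
    "<fdr_result> %d / %d significant at FDR q = %g (p <= %.3g)\n",
    x$n_significant, length(x$mask), x$q, x$p_threshold
  ))
  invisible(x)
}

#' Tidy an FDR result
#' @param x An `fdr_result` from [bh_fdr()].
#' @param ... Unused.
#' @return Tibble: `voxel_id`, `p`, `significant`.
#' @export
tidy.fdr_result <- function(x, ...) {
  tibble::tibble(
    voxel_id = names(x$pvals) %||% paste0("v", seq_along(x$pvals)),
    p = unname(x$pvals), significant = unname(x$mask)
  )
}

#' Overlap between two significance masks
#'
#' Proportion significant in each mask and their Jaccard overlap (the two
#' masks must cover the same voxels, in the same order). Two empty masks are
#' identical, so their Jaccard overlap is 1.
#'
#' @param mask_a,mask_b Logical vectors of equal length.
#' @return One-row tibble: `prop_a`, `prop_b`, `jaccard`.
#' @export
map_overlap <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) abort("masks differ in length")
  mask_a <- as.logical(mask_a)
  mask_b <- as.logical(mask_b)
  inter <- sum(mask_a & mask_b)
  uni <- sum(mask_a | mask_b)
  tibble::tibble(
    prop_a = mean(mask_a), prop_b = mean(mask_b),
    jaccard = if (uni == 0) 1 else inter / uni
  )
}

#' Write a voxelwise FDR result as TSV
#' @param fdr An `fdr_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fdr_result <- function(fdr, path) {
  readr::write_tsv(tidy(fdr), path, progress = FALSE)
  invisible(path)
}
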