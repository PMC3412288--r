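# Partial-F machinery shared by the OLS and mixed-model tests. Cfull is the
# complete reduced-model design (intercept included, possibly whitened).
partial_f_core <- function(y, S, Cfull, rank_tol = 1e-8) {
  N <- length(y)
  c_dim <- qr(Cfull)$rank
  qc <- qr.Q(qr(Cfull))[, seq_len(c_dim), drop = FALSE]
  y_perp <- y - qc %*% crossprod(qc, y)
  S <- as.matrix(S)
  S_perp <- S - qc %*% crossprod(qc, S)
  qrS <- qr(S_perp)
  # rank relative to the scale of the ORIGINAL block, so columns annihilated
  # by the covariate projection register as aliased
  scale_ref <- max(sqrt(colSums(S^2)), .Machine$double.eps)
  df1 <- sum(abs(diag(qrS$qr)[seq_len(min(dim(S_perp)))]) > rank_tol * scale_ref)
  n_aliased <- ncol(S) - df1
  rss_red <- sum(y_perp^2)
  df2 <- N - c_dim - df1
  if (df1 == 0) {
    return(tibble::tibble(
      F = 0, df1 = 0L, df2 = as.integer(N - c_dim), p = 1,
      n_aliased = as.integer(n_aliased)
    ))
  }
  if (df2 <= 0) abort("not enough observations: N <= covariates + selected SNPs")
  qs <- qr.Q(qrS)[, seq_len(df1), drop = FALSE]
  fitted_norm2 <- sum(crossprod(qs, y_perp)^2)
  rss_full <- max(rss_red - fitted_norm2, 0)
  if (rss_full <= rank_tol^2 * max(rss_red, 1)) {
    warn("full model fits perfectly; p-value floored at the smallest positive double")
    return(tibble::tibble(
      F = Inf, df1 = as.integer(df1), df2 = as.integer(df2),
      p = .Machine$double.xmin, n_aliased = as.integer(n_aliased)
    ))
  }
  Fstat <- (fitted_norm2 / df1) / (rss_full / df2)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  if (p == 0) p <- .Machine$double.xmin
  tibble::tibble(
    F = Fstat, df1 = as.integer(df1), df2 = as.integer(df2), p = p,
    n_aliased = as.integer(n_aliased)
  )
}

# Build the full reduced-model design: intercept plus covariates.
design_with_intercept <- function(C, N) {
  if (is.null(C)) return(matrix(1, N, 1))
  C <- as.matrix(C)
  if (nrow(C) != N) abort("covariate rows do not match observations")
  cbind(`(Intercept)` = 1, C)
}

#' Partial F-test of a SNP block against a covariates-only model
#'
#' Nested-model F-test comparing the full regression (intercept, covariates
#' and the selected SNP block) to the reduced regression (intercept and
#' covariates only). The numerator degrees of freedom equal the rank of the
#' SNP block after projecting out the covariates; columns aliased with the
#' covariates or with each other are dropped in column order. A block that is
#' entirely aliased (rank 0) returns `p = 1` by the empty-selection
#' convention. A perfectly fitting full model returns the smallest positive
#' double as the p-value, with a warning.
#'
#' @param y Numeric phenotype vector.
#' @param S SNP dosage block (N x k matrix or vector).
#' @param C Covariate matrix (N x c), without an intercept column; an
#'   intercept is always included in both models. `NULL` means
#'   intercept-only covariates.
#' @return One-row tibble: `F`, `df1`, `df2`, `p`, `n_aliased`.
#' @export
partial_f_test <- function(y, S, C = NULL) {
  y <- as.numeric(y)
  S <- as.matrix(S)
  if (nrow(S) != length(y)) abort("S rows do not match length of y")
  partial_f_core(y, S, design_with_intercept(C, length(y)))
}

#' Bonferroni threshold for gene-level significance
#'
#' Genome-wide gene-centric significance threshold `alpha / n_genes`, e.g.
#' `0.05 / 18284 = 2.73e-6` when all autosomal genes are tested.
#'
#' @param alpha Family-wise error rate.
#' @param n_genes Number of genes tested genome-wide.
#' @return The per-gene p-value threshold.
#' @export
bonferroni_gene_threshold <- function(alpha = 0.05, n_genes) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1) {
    abort("n_genes must be a positive count")
  }
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  alpha / n_genes
}

#' Ancestry components from genotypes
#'
#' Top principal components of the column-standardized dosage matrix, the
#' usual stand-in for population-structure covariates (MDS components serve
#' the same role). Monomorphic SNPs are skipped.
#'
#' @param g A [genotype_matrix()].
#' @param k Number of components (default 4).
#' @return Tibble: `subject_id`, `PC1` ... `PCk`.
#' @export
genotype_pcs <- function(g, k = 4) {
  d <- g$dosages
  sds <- apply(d, 2, sd)
  Z <- scale(d[, sds > 0, drop = FALSE])
  k <- min(k, nrow(Z) - 1, ncol(Z))
  pc <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = k)
  out <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  names(out) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble::tibble(subject_id = rownames(d)), out)
}

# Extract y and covariate matrix from a phenotype tibble.
extract_design <- function(phenotypes, phenotype, covariates) {
  if (!phenotype %in% names(phenotypes)) {
    abort(paste0("phenotype column not found: ", phenotype))
  }
  y <- as.numeric(phenotypes[[phenotype]])
  C <- NULL
  if (length(covariates) > 0) {
    missing_cov <- setdiff(covariates, names(phenotypes))
    if (length(missing_cov) > 0) {
      abort(paste0("covariate column(s) not found: ", paste(missing_cov, collapse = ", ")))
    }
    C <- as.matrix(phenotypes[, covariates, drop = FALSE])
    storage.mode(C) <- "double"
  }
  list(y = y, C = C)
}

# Residuals of y on [1, C].
residualize <- function(y, C) {
  Cfull <- design_with_intercept(C, length(y))
  qc <- qr(Cfull)
  as.numeric(qr.resid(qc, y))
}

#' Gene-by-gene LASSO selection and joint partial F-tests
#'
#' The discovery scan. Per gene: the phenotype is residualized on the
#' covariates, a sparse SNP subset is chosen by cross-validated LASSO
#' ([select_snps()]), and the joint effect of the selected SNPs is tested by
#' a partial F-test in which the full model refits covariates plus the
#' selected dosages against the covariates-only reduced model (the LASSO
#' acts purely as a filter; its coefficients are not reused). Genes with an
#' empty selection get `p = 1`. Gene-level significance is declared at the
#' Bonferroni threshold `alpha / n_genes`.
#'
#' @param g A QC'ed [genotype_matrix()], subject-aligned with `phenotypes`
#'   (see [join_cohort()]).
#' @param map A `gene_map` (SNPs absent from `g` are ignored, with a
#'   message).
#' @param phenotypes Subject-aligned tibble with the phenotype and covariate
#'   columns.
#' @param phenotype Name of the phenotype column.
#' @param covariates Character vector of covariate column names (e.g. age,
#'   sex, ancestry components), or `NULL`.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param n_genes Bonferroni denominator; defaults to the number of genes
#'   tested here, but should be the genome-wide gene count when this scan is
#'   a subset.
#' @param n_folds,n_lambda,lambda_min_ratio,seed,tol,max_iter Passed to
#'   [select_snps()].
#' @return Tibble of class `gene_scan` sorted by p-value, columns `gene_id`,
#'   `n_snps_total`, `n_snps_selected`, `F`, `df1`, `df2`, `p`,
#'   `significant`; attributes `alpha`, `n_genes`, `threshold`.
#' @export
gene_scan <- function(g, map, phenotypes, phenotype = "phenotype",
                      covariates = NULL, alpha = 0.05, n_genes = NULL,
                      n_folds = NULL, n_lambda = 100, lambda_min_ratio = 1e-3,
                      seed = NULL, tol = 1e-7, max_iter = 10000) {
  stopifnot(identical(subject_ids(g), phenotypes$subject_id))
  des <- extract_design(phenotypes, phenotype, covariates)
  y <- des$y
  C <- des$C
  y_resid <- residualize(y, C)
  map <- dplyr::filter(tibble::as_tibble(map), .data$snp_id %in% colnames(g$dosages))
  if (nrow(map) == 0) abort("no gene-map SNPs present in the genotypes")
  genes <- sort(unique(map$gene_id))
  if (is.null(n_genes)) n_genes <- length(genes)
  threshold <- bonferroni_gene_threshold(alpha, n_genes)
  rows <- purrr::map(genes, function(gid) {
    snps <- map$snp_id[map$gene_id == gid]
    Gg <- g$dosages[, snps, drop = FALSE]
    fit <- suppressMessages(select_snps(Gg, y_resid,
      n_folds = n_folds, n_lambda = n_lambda,
      lambda_min_ratio = lambda_min_ratio, seed = seed,
      tol = tol, max_iter = max_iter
    ))
    if (length(fit$selected) == 0) {
      c_dim <- 1L + if (is.null(C)) 0L else ncol(C)
      ft <- tibble::tibble(
        F = 0, df1 = 0L, df2 = as.integer(length(y) - c_dim),
        p = 1, n_aliased = 0L
      )
    } else {
      ft <- partial_f_test(y, Gg[, fit$selected, drop = FALSE], C)
    }
    tibble::tibble(
      gene_id = gid, n_snps_total = length(snps),
      n_snps_selected = length(fit$selected),
      F = ft$F, df1 = ft$df1, df2 = ft$df2, p = ft$p
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = .data$p < threshold) |>
    dplyr::arrange(.data$p, .data$gene_id)
  attr(out, "alpha") <- alpha
  attr(out, "n_genes") <- n_genes
  attr(out, "threshold") <- threshold
  class(out) <- c("gene_scan", class(out))
  out
}

#' @export
print.gene_scan <- function(x, ...) {
  cat(sprintf(
    "<gene_scan> %d genes, %d significant at p < %.3g (Bonferroni, %d genes)\n",
    nrow(x), sum(x$significant), attr(x, "threshold"), attr(x, "n_genes")
  ))
  NextMethod()
}

#' Summarize a gene scan
#' @param x A `gene_scan` result.
#' @param ... Unused.
#' @return One-row tibble: number of genes, Bonferroni threshold, number of
#'   significant genes, top gene and its p-value.
#' @export
glance.gene_scan <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x), threshold = attr(x, "threshold"),
    n_significant = sum(x$significant),
    top_gene = x$gene_id[1], top_p = x$p[1]
  )
}

#' Plot a gene scan
#'
#' Gene-level Manhattan-style plot: `-log10(p)` per gene with the Bonferroni
#' threshold as a dashed line.
#'
#' @param object A `gene_scan` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_scan <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$gene_id) |>
    dplyr::mutate(idx = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$idx, y = -log10(.data$p),
    colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "threshold")),
      linetype = 2
    ) +
    ggplot2::labs(
      x = "gene (alphabetical)", y = expression(-log[10](p)),
      title = "Gene-based joint association scan"
    ) +
    ggplot2::guides(colour = "none")
}

#' Per-SNP univariate association scan
#'
#' The single-SNP GWAS baseline: for each SNP, the t-test of the additive
#' dosage coefficient in a linear model with the covariates. Monomorphic
#' SNPs return `beta = 0`, `p = 1`.
#'
#' @inheritParams gene_scan
#' @return Tibble: `snp_id`, `chrom`, `pos`, `beta`, `t`, `p`.
#' @export
univariate_scan <- function(g, phenotypes, phenotype = "phenotype",
                            covariates = NULL) {
  stopifnot(identical(subject_ids(g), phenotypes$subject_id))
  des <- extract_design(phenotypes, phenotype, covariates)
  N <- length(des$y)
  Cfull <- design_with_intercept(des$C, N)
  qc <- qr(Cfull)
  y_perp <- as.numeric(qr.resid(qc, des$y))
  X_perp <- qr.resid(qc, g$dosages)
  xss <- colSums(X_perp^2)
  df <- N - qc$rank - 1L
  if (df <= 0) abort("not enough observations for the univariate scan")
  beta <- ifelse(xss > 0, colSums(X_perp * y_perp) / xss, 0)
  rss <- sum(y_perp^2) - beta^2 * xss
  se <- sqrt(pmax(rss, 0) / df / ifelse(xss > 0, xss, 1))
  t <- ifelse(xss > 0 & se > 0, beta / se, 0)
  p <- 2 * pt(-abs(t), df)
  p[xss == 0] <- 1
  p <- pmax(p, .Machine$double.xmin)
  tibble::tibble(
    snp_id = g$snps$snp_id, chrom = g$snps$chrom, pos = g$snps$pos,
    beta = unname(beta), t = unname(t), p = unname(p)
  )
}

#' Per-gene minimum univariate p-value
#'
#' The single-SNP gene summary used as the baseline against the joint
#' LASSO + F-test scan: for each gene, the smallest univariate p-value over
#' its member SNPs.
#'
#' @param univariate Result of [univariate_scan()].
#' @param map A `gene_map`.
#' @return Tibble: `gene_id`, `min_p`, `top_snp`, `n_snps`.
#' @export
gene_min_p <- function(univariate, map) {
  tibble::as_tibble(map) |>
    dplyr::inner_join(univariate, by = "snp_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      min_p = min(.data$p),
      top_snp = .data$snp_id[which.min(.data$p)],
      n_snps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene_id)
}

#' Nested cross-validated gene scan
#'
#' The honest variant of the in-sample select-then-test scheme: SNP
#' selection is performed on one part of the cohort and the partial F-test
#' on the disjoint remainder, so selection and testing never see the same
#' subjects. Two schemes are provided: `fifth_folds` selects on each fifth
#' in turn and tests on the remaining four fifths (5 p-values averaged);
#' `half_split` selects on a random half and tests on the other half,
#' averaged over `n_trials` random splits. A split with an empty selection
#' contributes `p = 1`.
#'
#' @inheritParams gene_scan
#' @param scheme `"fifth_folds"` or `"half_split"`.
#' @param n_trials Number of random half-splits (ignored for
#'   `fifth_folds`).
#' @param seed Integer seed controlling the partitions; results are
#'   reproducible given the seed.
#' @return Tibble: `gene_id`, `p_avg`, `mean_n_selected`, `scheme`.
#' @export
nested_cv_scan <- function(g, map, phenotypes, phenotype = "phenotype",
                           covariates = NULL,
                           scheme = c("fifth_folds", "half_split"),
                           n_trials = 10, seed = 1, n_folds = NULL,
                           n_lambda = 100, lambda_min_ratio = 1e-3,
                           tol = 1e-7, max_iter = 10000) {
  scheme <- match.arg(scheme)
  stopifnot(identical(subject_ids(g), phenotypes$subject_id))
  des <- extract_design(phenotypes, phenotype, covariates)
  y <- des$y
  C <- des$C
  N <- length(y)
  map <- dplyr::filter(tibble::as_tibble(map), .data$snp_id %in% colnames(g$dosages))
  genes <- sort(unique(map$gene_id))
  partitions <- withr::with_seed(seed, {
    if (scheme == "fifth_folds") {
      fold <- sample(rep_len(1:5, N))
      lapply(1:5, function(f) list(sel = which(fold == f), test = which(fold != f)))
    } else {
      lapply(seq_len(n_trials), function(t) {
        half <- sample.int(N, floor(N / 2))
        list(sel = half, test = setdiff(seq_len(N), half))
      })
    }
  })
  rows <- purrr::map(genes, function(gid) {
    snps <- map$snp_id[map$gene_id == gid]
    Gg <- g$dosages[, snps, drop = FALSE]
    res <- purrr::map(partitions, function(part) {
      y_sel <- y[part$sel]
      C_sel <- if (is.null(C)) NULL else C[part$sel, , drop = FALSE]
      y_resid_sel <- residualize(y_sel, C_sel)
      fit <- suppressMessages(select_snps(
        Gg[part$sel, , drop = FALSE], y_resid_sel,
        n_folds = n_folds, n_lambda = n_lambda,
        lambda_min_ratio = lambda_min_ratio, tol = tol, max_iter = max_iter
      ))
      if (length(fit$selected) == 0) {
        return(list(p = 1, k = 0L))
      }
      C_test <- if (is.null(C)) NULL else C[part$test, , drop = FALSE]
      ft <- partial_f_test(
        y[part$test], Gg[part$test, fit$selected, drop = FALSE], C_test
      )
      list(p = ft$p, k = length(fit$selected))
    })
    tibble::tibble(
      gene_id = gid,
      p_avg = mean(purrr::map_dbl(res, "p")),
      mean_n_selected = mean(purrr::map_dbl(res, "k")),
      scheme = scheme
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$p_avg, .data$gene_id)
}

#' Write gene-scan results as TSV
#' @param scan A `gene_scan` result (or any tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_scan <- function(scan, path) {
  readr::write_tsv(tibble::as_tibble(scan), path, progress = FALSE)
  invisible(path)
}
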