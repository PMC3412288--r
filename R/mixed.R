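#' Realized-relationship (kinship) matrix from genotypes
#'
#' `K = Z Z' / M` with `Z` the column-standardized dosage matrix over the
#' `M` polymorphic SNPs: the standard genomic-relationship estimator, with
#' diagonal approximately 1 in expectation. Negative eigenvalues below
#' numerical noise are clipped to zero.
#'
#' @param g A [genotype_matrix()] (ideally genome-wide, post-QC).
#' @return Symmetric positive semidefinite matrix with subject-id dimnames.
#' @export
kinship_from_genotypes <- function(g) {
  d <- g$dosages
  sds <- apply(d, 2, sd)
  Z <- scale(d[, sds > 0, drop = FALSE])
  if (ncol(Z) < 2) abort("at least 2 polymorphic SNPs are required")
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 0) {
    K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- list(rownames(d), rownames(d))
  }
  K
}

#' Read / write a kinship matrix as square TSV
#'
#' Square tab-separated table: header row of subject ids, first column
#' `subject_id`, symmetric numeric entries.
#'
#' @param path File path.
#' @return For `read_kinship()`, a symmetric numeric matrix with subject-id
#'   dimnames.
#' @export
read_kinship <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tab[[1]])
  K <- as.matrix(tab[, -1])
  storage.mode(K) <- "double"
  rownames(K) <- ids
  if (!identical(colnames(K), ids)) abort("kinship row and column ids disagree")
  if (max(abs(K - t(K))) > 1e-10) abort("kinship matrix is not symmetric")
  (K + t(K)) / 2
}

#' @rdname read_kinship
#' @param K Symmetric kinship matrix with subject-id dimnames.
#' @export
write_kinship <- function(K, path) {
  tab <- tibble::as_tibble(K, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(K)), tab)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Eigen-rotation pieces reused across many tests on the same cohort: the
# eigendecomposition of K (for whitening) and of S (K + I) S with
# S = I - X (X'X)^-1 X' under the reduced design (for REML).
mixed_model_prep <- function(K, Cfull) {
  N <- nrow(K)
  eig_K <- eigen(K, symmetric = TRUE)
  eig_K$values <- pmax(eig_K$values, 0)
  qx <- qr(Cfull)
  q <- qx$rank
  Qx <- qr.Q(qx)[, seq_len(q), drop = FALSE]
  SKS <- K + diag(N)
  SKS <- SKS - Qx %*% crossprod(Qx, SKS)
  SKS <- SKS - (SKS %*% Qx) %*% t(Qx)
  SKS <- (SKS + t(SKS)) / 2
  eR <- eigen(SKS, symmetric = TRUE)
  keep <- seq_len(N - q)
  list(
    eig_K = eig_K, q = q,
    xi = pmax(eR$values[keep] - 1, -1 + 1e-12),
    U_R = eR$vectors[, keep, drop = FALSE]
  )
}

# Restricted log-likelihood at a given delta = sigma_e^2 / sigma_g^2, on the
# rotated residual scale (eta = U_R' y, xi the rotated eigenvalues).
reml_loglik <- function(delta, eta2, xi) {
  nq <- length(xi)
  denom <- xi + delta
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(sum(eta2 / denom)) -
    sum(log(denom)))
}

#' REML variance components under a kinship model
#'
#' Estimates the variance-ratio `delta = sigma_e^2 / sigma_g^2` of the model
#' `y ~ N(X b, sigma_g^2 K + sigma_e^2 I)` by restricted maximum likelihood
#' on the eigen-rotated data (the spectral trick of efficient mixed-model
#' association): a grid of 100 log-spaced points on `[1e-5, 1e5]` is scored
#' and the best bracket refined by golden-section search. A likelihood that
#' is maximized at the upper grid bound (`sigma_g^2 -> 0`) is reported with a
#' warning; the model then degenerates to ordinary least squares.
#'
#' @param y Phenotype vector.
#' @param X Fixed-effects design matrix including the intercept (the reduced,
#'   covariates-only model).
#' @param K Kinship matrix, or a prepared object from the internal
#'   eigen-rotation (reused across phenotypes for speed).
#' @param n_grid Number of grid points.
#' @param bounds Grid range for `delta`.
#' @return List of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `delta`, `reml_loglik`, `boundary` (logical).
#' @export
reml_delta <- function(y, X, K, n_grid = 100, bounds = c(1e-5, 1e5)) {
  prep <- if (is.list(K) && !is.null(K$xi)) K else {
    mixed_model_prep(as.matrix(K), as.matrix(X))
  }
  eta2 <- as.numeric(crossprod(prep$U_R, y))^2
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  ll <- vapply(grid, reml_loglik, numeric(1), eta2 = eta2, xi = prep$xi)
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, n_grid)]
  opt <- optimize(function(ld) reml_loglik(exp(ld), eta2, prep$xi),
    interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-10
  )
  delta <- exp(opt$maximum)
  best_ll <- opt$objective
  if (ll[i] > best_ll) {
    delta <- grid[i]
    best_ll <- ll[i]
  }
  boundary <- i == n_grid
  if (boundary) {
    warn("REML likelihood flat in the genetic variance; delta at the upper bound (OLS-equivalent)")
    delta <- bounds[2]
    best_ll <- ll[n_grid]
  }
  nq <- length(prep$xi)
  sigma_g2 <- sum(eta2 / (prep$xi + delta)) / nq
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2, delta = delta,
    reml_loglik = best_ll, boundary = boundary
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> sigma_g2 = %.4g, sigma_e2 = %.4g (delta = %.4g)\n",
    x$sigma_g2, x$sigma_e2, x$delta
  ))
  invisible(x)
}

#' Mixed-model partial F-test allowing for relatedness
#'
#' The partial F-test of a selected SNP block generalized to related
#' subjects: variance components of `sigma_g^2 K + sigma_e^2 I` are
#' estimated once by REML under the reduced (covariates-only) model, the
#' phenotype, SNP block, intercept and covariates are whitened through the
#' eigenbasis of `K`, and the ordinary partial F machinery is applied to the
#' whitened data (the single-estimation approximation of efficient
#' mixed-model association). With `K = I` the result reduces exactly to
#' [partial_f_test()].
#'
#' @inheritParams partial_f_test
#' @param K Kinship matrix aligned with `y` (subject order), or a prepared
#'   decomposition from a previous call (see `prep`).
#' @param prep Optional precomputed rotation returned in the `prep` attribute
#'   of an earlier result on the same `K` and `C`; avoids repeating the
#'   eigendecompositions when many phenotypes are tested.
#' @return One-row tibble: `F`, `df1`, `df2`, `p`, `n_aliased`, `delta`,
#'   `sigma_g2`, `sigma_e2`; attribute `prep` carries the reusable rotation.
#' @export
mixed_partial_f_test <- function(y, S, C = NULL, K, prep = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  Cfull <- design_with_intercept(C, N)
  if (is.null(prep)) prep <- mixed_model_prep(as.matrix(K), Cfull)
  vc <- reml_delta(y, Cfull, prep)
  # whitening: V^(-1/2) = U diag(1/sqrt(d + delta)) U', up to sigma_g which
  # cancels in the F ratio
  w <- 1 / sqrt(prep$eig_K$values + vc$delta)
  U <- prep$eig_K$vectors
  whiten <- function(M) U %*% (w * crossprod(U, M))
  yw <- as.numeric(whiten(matrix(y)))
  Sw <- whiten(as.matrix(S))
  Cw <- whiten(Cfull)
  out <- partial_f_core(yw, Sw, Cw)
  out$delta <- vc$delta
  out$sigma_g2 <- vc$sigma_g2
  out$sigma_e2 <- vc$sigma_e2
  attr(out, "prep") <- prep
  out
}
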