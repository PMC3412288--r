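#' Soft-thresholding operator
#'
#' The scalar update at the heart of coordinate-descent for L1-penalized
#' least squares: `sign(z) * max(|z| - gamma, 0)`.
#'
#' @param z Numeric vector.
#' @param gamma Non-negative threshold.
#' @return Numeric vector, same length as `z`.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) abort("gamma must be non-negative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' LASSO fit at a single penalty by cyclic coordinate descent
#'
#' Minimizes `(1/(2N)) ||y - X b||^2 + lambda ||b||_1` by cyclic coordinate
#' descent with exact soft-threshold updates. Columns of `X` should be
#' standardized (mean 0, unit variance) and `y` centered; constant columns
#' must be removed beforehand. Convergence is declared when the largest
#' coefficient change in a sweep falls below `tol`; the Karush-Kuhn-Tucker
#' residual of the returned solution is attached as attribute `kkt`.
#'
#' @param X Standardized design matrix (N x m).
#' @param y Centered response vector.
#' @param lambda Positive penalty (on the `1/(2N)` loss scale).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum number of full sweeps.
#' @param beta_init Optional warm-start coefficient vector.
#' @return Numeric coefficient vector of length `ncol(X)` with attribute
#'   `kkt` (maximum stationarity violation).
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-7, max_iter = 10000,
                      beta_init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("X and y dimensions disagree")
  if (lambda < 0) abort("lambda must be non-negative")
  if (is.null(beta_init)) beta_init <- numeric(ncol(X))
  fit <- .cd_lasso(X, y, lambda, beta_init, tol, as.integer(max_iter))
  if (!fit$converged) {
    abort(sprintf(
      "coordinate descent did not converge in %d sweeps (KKT violation %.3e)",
      max_iter, fit$kkt
    ))
  }
  structure(as.numeric(fit$beta), kkt = fit$kkt)
}

#' Penalty path for a LASSO problem
#'
#' Log-spaced sequence of `n_points` penalties from `lambda_max` (the
#' smallest penalty at which all coefficients are exactly zero,
#' `max |X'y| / N`) down to `ratio * lambda_max`. A response orthogonal to
#' every column gives `lambda_max = 0` and a single-point path.
#'
#' @param X Standardized design matrix.
#' @param y Centered response.
#' @param n_points Number of path points.
#' @param ratio Ratio of the smallest to the largest penalty.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(X, y, n_points = 100, ratio = 1e-3) {
  X <- as.matrix(X)
  lambda_max <- max(abs(crossprod(X, y))) / nrow(X)
  if (lambda_max == 0) return(0)
  path <- exp(seq(log(lambda_max), log(ratio * lambda_max), length.out = n_points))
  # first point sits at lambda_max (with one part in 1e10 of slack against
  # summation-order rounding) so the first fit is exactly the zero model
  path[1] <- lambda_max * (1 + 1e-10)
  path
}

#' Cross-validated penalty selection
#'
#' For every point of the penalty path, the model is refit with one fold held
#' out (leave-one-out by default, the deterministic scheme; k-fold assignment
#' is randomized under `seed`) and the held-out squared prediction error is
#' averaged over subjects. Within each training fold the columns and the
#' response are re-centered and the training intercept is used for
#' prediction. The selected penalty minimizes the CV mean squared error;
#' ties go to the larger penalty (the sparser model).
#'
#' @param X Standardized design matrix.
#' @param y Centered response.
#' @param n_folds Number of folds, or `NULL` for leave-one-out.
#' @param lambdas Penalty path; defaults to [lambda_path()] of `X`, `y`.
#' @param seed Integer seed for k-fold assignment (ignored for leave-one-out).
#' @param tol,max_iter Passed to the coordinate-descent solver.
#' @return List with `lambda_star`, `cv_mse` (per path point) and `lambdas`.
#' @export
cv_select_lambda <- function(X, y, n_folds = NULL, lambdas = NULL,
                             seed = NULL, tol = 1e-7, max_iter = 10000) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  if (N < 3) abort("at least 3 observations are required for cross-validation")
  if (is.null(lambdas)) lambdas <- lambda_path(X, y)
  if (is.null(n_folds)) {
    fold_id <- seq_len(N)
    n_folds <- N
  } else {
    if (n_folds > N) abort("more folds than observations")
    perm <- if (is.null(seed)) {
      sample.int(N)
    } else {
      withr::with_seed(seed, sample.int(N))
    }
    fold_id <- integer(N)
    fold_id[perm] <- rep_len(seq_len(n_folds), N)
  }
  sse <- .cd_lasso_cv(X, y, lambdas, as.integer(fold_id),
    as.integer(n_folds), tol, as.integer(max_iter)
  )
  cv_mse <- as.numeric(sse) / N
  list(
    lambda_star = lambdas[which.min(cv_mse)],
    cv_mse = cv_mse, lambdas = lambdas
  )
}

#' Select a sparse SNP subset within one gene
#'
#' The per-gene selection step: dosage columns are standardized internally,
#' the penalty is chosen by cross-validated mean squared error
#' (leave-one-out by default) on the covariate-adjusted phenotype, the model
#' is refit on the full data along a warm-started path down to the selected
#' penalty, and coefficients are returned on the original dosage scale. The
#' nonzero-coefficient SNPs form the gene's selected subset. Constant
#' columns are dropped (with a message); a gene whose columns are all
#' constant yields an empty selection. Exactly duplicated columns resolve
#' deterministically to the lowest column index because coordinate updates
#' cycle in fixed column order.
#'
#' @param G_gene Dosage matrix for one gene (subjects x SNPs, named columns).
#' @param y_resid Covariate-adjusted phenotype (residuals of the phenotype on
#'   the covariates; centered).
#' @param n_folds Folds for [cv_select_lambda()]; `NULL` = leave-one-out.
#' @param n_lambda,lambda_min_ratio Path size and span, see [lambda_path()].
#' @param seed Seed for k-fold CV assignment; unused for leave-one-out.
#' @param tol,max_iter Coordinate-descent controls.
#' @return An object of class `lasso_fit`: list with `beta` (dosage-scale
#'   coefficients, named), `selected` (integer indices of nonzero
#'   coefficients), `snp_ids`, `lambda_star`, `lambdas`, `cv_mse`, and
#'   `dropped_constant` (ids of constant columns removed).
#' @export
select_snps <- function(G_gene, y_resid, n_folds = NULL, n_lambda = 100,
                        lambda_min_ratio = 1e-3, seed = NULL,
                        tol = 1e-7, max_iter = 10000) {
  G_gene <- as.matrix(G_gene)
  if (is.null(colnames(G_gene))) {
    colnames(G_gene) <- paste0("snp", seq_len(ncol(G_gene)))
  }
  y <- as.numeric(y_resid)
  y <- y - mean(y)
  sds <- apply(G_gene, 2, sd)
  keep <- sds > 0
  dropped <- colnames(G_gene)[!keep]
  if (length(dropped) > 0) {
    inform(sprintf("dropped %d constant SNP column(s) in gene", length(dropped)))
  }
  empty <- function() {
    structure(list(
      beta = setNames(numeric(ncol(G_gene)), colnames(G_gene)),
      selected = integer(0), snp_ids = colnames(G_gene),
      lambda_star = NA_real_, lambdas = numeric(0), cv_mse = numeric(0),
      dropped_constant = dropped
    ), class = "lasso_fit")
  }
  if (!any(keep)) return(empty())
  Xs <- scale(G_gene[, keep, drop = FALSE])
  # exactly duplicated standardized columns: the L1 solution splits weight
  # arbitrarily across them, so keep only the lowest-index copy (documented
  # tie-break); the removed copies report a zero coefficient
  col_scales <- attr(Xs, "scaled:scale")
  dup <- duplicated(lapply(seq_len(ncol(Xs)), function(j) Xs[, j]))
  if (any(dup)) {
    inform(sprintf("dropped %d duplicated SNP column(s) in gene", sum(dup)))
    keep[keep] <- !dup
    Xs <- Xs[, !dup, drop = FALSE]
    col_scales <- col_scales[!dup]
  }
  lambdas <- lambda_path(Xs, y, n_points = n_lambda, ratio = lambda_min_ratio)
  if (identical(lambdas, 0)) return(empty())
  cv <- cv_select_lambda(Xs, y,
    n_folds = n_folds, lambdas = lambdas, seed = seed,
    tol = tol, max_iter = max_iter
  )
  l_idx <- which(lambdas == cv$lambda_star)[1]
  path <- .cd_lasso_path(Xs, y, lambdas[seq_len(l_idx)], tol, as.integer(max_iter))
  if (!path$converged) {
    abort("coordinate descent did not converge along the penalty path")
  }
  beta_std <- path$betas[, l_idx]
  # numerical zeros (e.g. from exactly collinear duplicates) are true zeros
  beta_std[abs(beta_std) < 1e-9] <- 0
  beta <- setNames(numeric(ncol(G_gene)), colnames(G_gene))
  beta[keep] <- beta_std / col_scales
  structure(list(
    beta = beta, selected = unname(which(beta != 0)),
    snp_ids = colnames(G_gene), lambda_star = cv$lambda_star,
    lambdas = lambdas, cv_mse = cv$cv_mse, dropped_constant = dropped
  ), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf(
    "<lasso_fit> %d / %d SNPs selected (lambda* = %s)\n",
    length(x$selected), length(x$snp_ids),
    ifelse(is.na(x$lambda_star), "NA", format(x$lambda_star, digits = 4))
  ))
  invisible(x)
}

#' Tidy a per-gene LASSO fit
#' @param x A `lasso_fit` from [select_snps()].
#' @param ... Unused.
#' @return Tibble with columns `snp_id`, `beta`, `selected`.
#' @export
tidy.lasso_fit <- function(x, ...) {
  tibble::tibble(
    snp_id = x$snp_ids, beta = unname(x$beta),
    selected = unname(x$beta != 0)
  )
}

#' @rdname tidy.lasso_fit
#' @return For `glance()`: one-row tibble with the selected penalty, the
#'   minimum CV error and the selection size.
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(
    lambda_star = x$lambda_star,
    cv_mse_min = if (length(x$cv_mse)) min(x$cv_mse) else NA_real_,
    n_snps = length(x$snp_ids),
    n_selected = length(x$selected)
  )
}

#' Plot the cross-validation curve of a per-gene LASSO fit
#' @param object A `lasso_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lasso_fit <- function(object, ...) {
  if (length(object$cv_mse) == 0) abort("fit has no CV curve (empty gene)")
  dat <- tibble::tibble(lambda = object$lambdas, cv_mse = object$cv_mse)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lambda, y = .data$cv_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda_star, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(lambda), y = "CV mean squared error",
      title = "Cross-validated penalty selection"
    )
}
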