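# Independent oracles used to cross-check the package's own implementations.
# Each deliberately avoids the code path it verifies.

# Lasso by exhaustive KKT enumeration over active sets and sign patterns.
# Minimizes (1/(2N)) ||y - X b||^2 + lambda ||b||_1; feasible for m <= 8.
lasso_enumerate <- function(X, y, lambda, tol = 1e-9) {
  X <- as.matrix(X)
  N <- nrow(X)
  m <- ncol(X)
  stopifnot(m <= 10)
  best <- NULL
  best_obj <- Inf
  obj <- function(b) sum((y - X %*% b)^2) / (2 * N) + lambda * sum(abs(b))
  for (code in 0:(3^m - 1)) {
    s <- integer(m)
    c0 <- code
    for (j in seq_len(m)) {
      s[j] <- (c0 %% 3) - 1 # -1, 0, +1
      c0 <- c0 %/% 3
    }
    A <- which(s != 0)
    b <- numeric(m)
    if (length(A) > 0) {
      XA <- X[, A, drop = FALSE]
      G <- crossprod(XA) / N
      if (rcond(G) < 1e-12) next
      bA <- solve(G, crossprod(XA, y) / N - lambda * s[A])
      if (any(sign(bA) != s[A])) next
      b[A] <- bA
    }
    r <- y - X %*% b
    grad <- as.numeric(crossprod(X, r)) / N
    if (any(abs(grad[s == 0]) > lambda + tol)) next
    o <- obj(b)
    if (o < best_obj) {
      best_obj <- o
      best <- b
    }
  }
  best
}

# Exact HWE p-value by direct summation of the conditional distribution of
# the heterozygote count (plain factorial formula, no recurrence).
hwe_brute <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_rare == 0 || n_rare == 2 * N) {
    return(1)
  }
  hets <- seq(n_rare %% 2, min(n_rare, 2 * N - n_rare), by = 2)
  pr <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- N - h - hom_r
    exp(
      h * log(2) +
        lfactorial(N) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
        lfactorial(n_rare) + lfactorial(2 * N - n_rare) - lfactorial(2 * N)
    )
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# Partial F-test via explicit projection (hat) matrices.
partial_f_oracle <- function(y, S, C) {
  N <- length(y)
  Cfull <- cbind(1, C)
  H_red <- Cfull %*% solve(crossprod(Cfull)) %*% t(Cfull)
  Xfull <- cbind(Cfull, S)
  H_full <- Xfull %*% solve(crossprod(Xfull)) %*% t(Xfull)
  rss_red <- sum(((diag(N) - H_red) %*% y)^2)
  rss_full <- sum(((diag(N) - H_full) %*% y)^2)
  df1 <- qr(Xfull)$rank - qr(Cfull)$rank
  df2 <- N - qr(Xfull)$rank
  F <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Dense-matrix restricted log-likelihood of y ~ N(Xb, sg2 (K + delta I)),
# profiled over sg2, as a function of delta. Direct determinant formula.
reml_dense <- function(delta, y, X, K) {
  N <- length(y)
  q <- qr(X)$rank
  H <- K + delta * diag(N)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  P <- Hi - Hi %*% X %*% solve(XtHiX) %*% t(X) %*% Hi
  yPy <- as.numeric(t(y) %*% P %*% y)
  sg2 <- yPy / (N - q)
  as.numeric(
    -0.5 * (determinant(H)$modulus + determinant(XtHiX)$modulus -
      determinant(crossprod(X))$modulus +
      (N - q) * log(2 * pi * sg2) + (N - q))
  )
}

# Plain-R cyclic coordinate descent (no warm starts), used to re-derive CV
# curves from scratch, independently of the compiled path code.
lasso_cd_r <- function(X, y, lambda, tol = 1e-10, max_iter = 50000) {
  N <- nrow(X)
  m <- ncol(X)
  beta <- numeric(m)
  xsq <- colSums(X^2) / N
  r <- y - X %*% beta
  for (it in seq_len(max_iter)) {
    maxdel <- 0
    for (j in seq_len(m)) {
      if (xsq[j] <= 0) next
      rho <- sum(X[, j] * r) / N + xsq[j] * beta[j]
      bnew <- sign(rho) * max(abs(rho) - lambda, 0) / xsq[j]
      del <- bnew - beta[j]
      if (del != 0) {
        r <- r - del * X[, j]
        beta[j] <- bnew
        maxdel <- max(maxdel, abs(del))
      }
    }
    if (maxdel < tol) break
  }
  beta
}

# CV curve re-derived from scratch: per-fold centering, fresh fits.
lasso_cv_r <- function(X, y, lambdas, fold_id) {
  N <- nrow(X)
  sse <- numeric(length(lambdas))
  for (f in sort(unique(fold_id))) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    xm <- colMeans(X[tr, , drop = FALSE])
    ym <- mean(y[tr])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, xm)
    ytr <- y[tr] - ym
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    yte <- y[te] - ym
    for (l in seq_along(lambdas)) {
      b <- lasso_cd_r(Xtr, ytr, lambdas[l])
      sse[l] <- sse[l] + sum((yte - Xte %*% b)^2)
    }
  }
  sse / N
}

# Tiny VCF writer for reader tests.
write_test_vcf <- function(path, sites, samples) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
  rows <- vapply(sites, function(s) {
    paste(c(
      s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".", "GT", s$gt
    ), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# Dosage matrix with exact genotype counts (n0 zeros, n1 hets, n2 homs).
dosage_from_counts <- function(n0, n1, n2) c(rep(0, n0), rep(1, n1), rep(2, n2))

# Small simulated gene + phenotype used across lasso/assoc tests.
toy_gene <- function(n = 100, m = 10, rho = 0.4, seed = 1) {
  cfg <- sim_config(
    n_subjects = n, genes = c(gene = m), ld_rho = rho,
    maf_range = c(0.2, 0.4), seed = seed
  )
  simulate_genotypes(cfg)
}
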