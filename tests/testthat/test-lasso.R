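test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-5, 2), -3)
  expect_equal(soft_threshold(1, 2), 0)
  expect_equal(soft_threshold(c(-1, 0, 4), 1), c(0, 0, 3))
  expect_error(soft_threshold(1, -1), "non-negative")
})

test_that("coordinate descent matches the orthonormal closed form", {
  withr::with_seed(101, {
    N <- 40
    m <- 5
    Q <- qr.Q(qr(matrix(rnorm(N * m), N, m)))
    X <- sqrt(N) * Q # X'X = N I
    y <- rnorm(N)
    for (lambda in c(0.01, 0.05, 0.2)) {
      b <- lasso_fit(X, y, lambda)
      closed <- soft_threshold(as.numeric(crossprod(X, y)) / N, lambda)
      expect_equal(as.numeric(b), closed, tolerance = 1e-6)
    }
  })
})

test_that("penalties at or above lambda_max give the exact zero solution", {
  withr::with_seed(102, {
    X <- scale(matrix(rnorm(200), 50, 4))
    y <- rnorm(50)
    y <- y - mean(y)
    lmax <- max(abs(crossprod(X, y))) / 50
    expect_identical(as.numeric(lasso_fit(X, y, lmax)), rep(0, 4))
    expect_identical(as.numeric(lasso_fit(X, y, 2 * lmax)), rep(0, 4))
  })
})

test_that("an unpenalized fit equals least squares", {
  withr::with_seed(103, {
    X <- scale(matrix(rnorm(300), 60, 5))
    y <- rnorm(60)
    y <- y - mean(y)
    b <- lasso_fit(X, y, 0, tol = 1e-10)
    ols <- solve(crossprod(X), crossprod(X, y))
    expect_equal(as.numeric(b), as.numeric(ols), tolerance = 1e-6)
  })
})

test_that("solutions agree with exhaustive KKT enumeration on small problems", {
  withr::with_seed(104, {
    for (i in 1:8) {
      N <- sample(15:30, 1)
      m <- sample(3:6, 1)
      X <- scale(matrix(rnorm(N * m), N, m))
      b_true <- numeric(m)
      b_true[1:2] <- c(1, -0.5)
      y <- as.numeric(X %*% b_true + rnorm(N))
      y <- y - mean(y)
      lambda <- runif(1, 0.05, 0.4)
      b <- lasso_fit(X, y, lambda, tol = 1e-9)
      b_oracle <- lasso_enumerate(X, y, lambda)
      expect_equal(as.numeric(b), as.numeric(b_oracle), tolerance = 1e-6)
      expect_lt(attr(b, "kkt"), 1e-7)
    }
  })
})

test_that("solutions agree with an independent penalized-regression library", {
  skip_if_not_installed("glmnet")
  withr::with_seed(105, {
    N <- 80
    m <- 12
    X <- scale(matrix(rnorm(N * m), N, m))
    y <- as.numeric(X[, 1] * 0.8 - X[, 5] * 0.4 + rnorm(N))
    y <- y - mean(y)
    for (lambda in c(0.02, 0.1, 0.3)) {
      b <- lasso_fit(X, y, lambda, tol = 1e-10)
      ref <- glmnet::glmnet(X, y,
        alpha = 1, lambda = lambda, standardize = FALSE,
        intercept = FALSE, thresh = 1e-14
      )
      expect_equal(as.numeric(b), as.numeric(ref$beta), tolerance = 1e-5)
    }
  })
})

test_that("the objective is non-increasing across sweeps and KKT holds", {
  withr::with_seed(106, {
    N <- 50
    m <- 8
    X <- scale(matrix(rnorm(N * m), N, m))
    y <- as.numeric(X %*% rnorm(m) + rnorm(N))
    y <- y - mean(y)
    lambda <- 0.1
    obj <- function(b) sum((y - X %*% b)^2) / (2 * N) + lambda * sum(abs(b))
    vals <- vapply(1:6, function(k) {
      fit <- genefscan:::.cd_lasso(X, y, lambda, numeric(m), 0, k)
      obj(fit$beta)
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
    # KKT at the converged solution
    b <- lasso_fit(X, y, lambda)
    r <- y - X %*% as.numeric(b)
    g <- as.numeric(crossprod(X, r)) / N
    nz <- as.numeric(b) != 0
    expect_true(all(abs(g[!nz]) <= lambda + 1e-6))
    expect_true(all(abs(g[nz] - lambda * sign(as.numeric(b)[nz])) <= 1e-6))
  })
})

test_that("the penalty path starts at the all-zero model and decreases", {
  withr::with_seed(107, {
    X <- scale(matrix(rnorm(400), 80, 5))
    y <- rnorm(80)
    y <- y - mean(y)
    path <- lambda_path(X, y, n_points = 50)
    expect_length(path, 50)
    expect_true(all(diff(path) < 0))
    expect_identical(as.numeric(lasso_fit(X, y, path[1])), rep(0, 5))
    # response orthogonal to every column: single-point degenerate path
    expect_identical(lambda_path(X, rep(0, 80)), 0)
  })
})

test_that("the support-size envelope grows as the penalty shrinks", {
  # over simulated genes, the running maximum of the support size along the
  # path (large to small penalty) is non-decreasing
  withr::with_seed(108, {
    for (i in 1:20) {
      g <- toy_gene(n = 60, m = 8, seed = 1000 + i)
      Xs <- scale(g$dosages)
      y <- as.numeric(Xs %*% c(0.6, -0.4, rep(0, 6)) + rnorm(60))
      y <- y - mean(y)
      lambdas <- lambda_path(Xs, y, n_points = 40)
      fit <- genefscan:::.cd_lasso_path(Xs, y, lambdas, 1e-7, 10000L)
      sizes <- colSums(fit$betas != 0)
      envelope <- cummax(sizes)
      expect_true(all(diff(envelope) >= 0))
      expect_equal(sizes[1], 0)
    }
  })
})

test_that("cross-validation selects the signal in the noiseless limit", {
  withr::with_seed(109, {
    N <- 50
    X <- scale(matrix(rnorm(N * 4), N, 4))
    y <- X[, 2] # exactly one standardized column
    cv <- cv_select_lambda(X, y)
    expect_equal(cv$lambda_star, min(cv$lambdas))
    b <- lasso_fit(X, y, cv$lambda_star)
    expect_gt(abs(as.numeric(b)[2]), 0.9)
  })
})

test_that("leave-one-out CV matches a from-scratch re-implementation", {
  withr::with_seed(110, {
    N <- 40
    m <- 6
    X <- scale(matrix(rnorm(N * m), N, m))
    y <- rnorm(N) # pure noise, independent of X
    y <- y - mean(y)
    lambdas <- lambda_path(X, y, n_points = 20)
    cv <- cv_select_lambda(X, y, lambdas = lambdas)
    cv_oracle <- lasso_cv_r(X, y, lambdas, fold_id = seq_len(N))
    expect_equal(cv$cv_mse, cv_oracle, tolerance = 1e-8)
    expect_equal(cv$lambda_star, lambdas[which.min(cv_oracle)])
  })
})

test_that("CV ties resolve to the larger penalty", {
  withr::with_seed(111, {
    X <- scale(matrix(rnorm(120), 30, 4))
    y <- rnorm(30)
    y <- y - mean(y)
    lmax <- max(abs(crossprod(X, y))) / 30
    # both penalties sit above lambda_max: identical all-zero models
    cv <- cv_select_lambda(X, y, lambdas = c(2 * lmax, 1.5 * lmax))
    expect_equal(cv$cv_mse[1], cv$cv_mse[2])
    expect_equal(cv$lambda_star, 2 * lmax)
  })
})

test_that("dosage-scale coefficients scale linearly with the response", {
  withr::with_seed(112, {
    g <- toy_gene(n = 80, m = 6, seed = 9)
    X <- scale(g$dosages)
    y <- as.numeric(X %*% c(1, rep(0, 5)) + rnorm(80))
    y <- y - mean(y)
    b1 <- lasso_fit(X, y, 0.1)
    b2 <- lasso_fit(X, 3 * y, 0.3)
    expect_equal(3 * as.numeric(b1), as.numeric(b2), tolerance = 1e-6)
  })
})

test_that("select_snps recovers an overwhelming single-SNP signal", {
  cfg <- sim_config(
    n_subjects = 200, genes = c(gA = 1),
    causal = data.frame(gene_id = "gA", snp_index = 1, effect = 1.0),
    noise_sd = 0.1, age_beta = 0, sex_beta = 0, seed = 31
  )
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  fit <- select_snps(g$dosages, ph$phenotype - mean(ph$phenotype))
  expect_equal(fit$selected, 1L)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(tidy(fit)$selected[1])
  expect_equal(glance(fit)$n_selected, 1L)
})

test_that("null genes frequently yield an empty or tiny selection", {
  sizes <- vapply(1:20, function(i) {
    cfg <- sim_config(
      n_subjects = 100, genes = c(gA = 10), age_beta = 0, sex_beta = 0,
      seed = 500 + i
    )
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(g, cfg)
    fit <- select_snps(g$dosages, ph$phenotype - mean(ph$phenotype))
    length(fit$selected)
  }, numeric(1))
  expect_gte(mean(sizes <= 2), 0.5)
  expect_lt(mean(sizes), 5)
})

test_that("duplicated SNP columns resolve to the lowest column index", {
  withr::with_seed(113, {
    g <- toy_gene(n = 150, m = 3, seed = 12)
    d <- cbind(g$dosages, dup = g$dosages[, 1])
    y <- as.numeric(scale(d[, 1])) * 1.5 + rnorm(150, 0, 0.3)
    fit <- select_snps(d, y - mean(y))
    expect_true(1L %in% fit$selected)
    expect_false(4L %in% fit$selected)
  })
})

test_that("constant columns are dropped and an all-constant gene is empty", {
  d <- cbind(a = rep(1, 30), b = c(rep(0, 15), rep(1, 15)))
  rownames(d) <- paste0("s", 1:30)
  y <- rnorm(30)
  expect_message(fit <- select_snps(d, y - mean(y)), "constant")
  expect_equal(fit$dropped_constant, "a")

  d2 <- cbind(a = rep(1, 30), b = rep(2, 30))
  rownames(d2) <- paste0("s", 1:30)
  fit2 <- suppressMessages(select_snps(d2, y - mean(y)))
  expect_length(fit2$selected, 0)
  expect_equal(unname(fit2$beta), c(0, 0))
})
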