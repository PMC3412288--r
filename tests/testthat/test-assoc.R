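test_that("partial F-test matches the explicit projection-matrix oracle", {
  withr::with_seed(207, {
    N <- 12
    C <- cbind(age = rnorm(N), sex = rbinom(N, 1, 0.5))
    S <- matrix(rbinom(N * 2, 2, 0.3), N, 2)
    y <- rnorm(N) + 0.5 * S[, 1]
    got <- partial_f_test(y, S, C)
    want <- partial_f_oracle(y, S, C)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2)
  })
})

test_that("a perfectly fitting SNP block floors the p-value", {
  withr::with_seed(208, {
    N <- 20
    C <- matrix(rnorm(N), N, 1)
    y <- rnorm(N)
    # S equals the residual of y on the covariates: RSS_full = 0
    S <- matrix(qr.resid(qr(cbind(1, C)), y), N, 1)
    expect_warning(res <- partial_f_test(y, S, C), "perfectly")
    expect_equal(res$p, .Machine$double.xmin)
  })
})

test_that("a SNP block aliased with the covariates returns p = 1", {
  withr::with_seed(209, {
    N <- 15
    C <- matrix(rnorm(N), N, 1)
    res <- partial_f_test(rnorm(N), S = C, C = C)
    expect_equal(res$df1, 0L)
    expect_equal(res$p, 1)
    expect_equal(res$n_aliased, 1L)
  })
})

test_that("aliased columns inside the block reduce df1 to the block rank", {
  withr::with_seed(210, {
    N <- 30
    S1 <- rbinom(N, 2, 0.4)
    S <- cbind(S1, 2 * S1, rbinom(N, 2, 0.3))
    res <- partial_f_test(rnorm(N), S, C = NULL)
    expect_equal(res$df1, 2L)
    expect_equal(res$n_aliased, 1L)
    expect_equal(res$df2, N - 1L - 2L)
  })
})

test_that("too few observations is an error", {
  expect_error(
    partial_f_test(rnorm(4), matrix(rnorm(16), 4, 4), NULL),
    "not enough observations"
  )
})

test_that("the partial F-test is invariant to reparameterizing covariates", {
  withr::with_seed(211, {
    N <- 40
    C <- matrix(rnorm(N * 3), N, 3)
    A <- matrix(c(2, 0, 1, 1, 3, 0, 0, -1, 1), 3, 3) # invertible
    S <- matrix(rbinom(N * 2, 2, 0.3), N, 2)
    y <- rnorm(N)
    r1 <- partial_f_test(y, S, C)
    r2 <- partial_f_test(y, S, C %*% A)
    expect_equal(r1$F, r2$F, tolerance = 1e-10)
    expect_equal(r1$df1, r2$df1)
  })
})

test_that("the Bonferroni gene threshold is alpha over the gene count", {
  expect_equal(signif(bonferroni_gene_threshold(0.05, 18284), 3), 2.73e-6)
  expect_equal(bonferroni_gene_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_gene_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_gene_threshold(0.05, 0), "positive")
})

test_that("univariate t-tests satisfy the t^2 = F identity", {
  withr::with_seed(212, {
    cfg <- sim_config(
      n_subjects = 80, genes = c(gA = 5),
      causal = data.frame(gene_id = "gA", snp_index = 2, effect = 0.5),
      seed = 41
    )
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(g, cfg)
    uni <- univariate_scan(g, ph, covariates = c("age", "sex"))
    C <- as.matrix(ph[, c("age", "sex")])
    for (j in seq_len(5)) {
      f1 <- partial_f_test(ph$phenotype, g$dosages[, j, drop = FALSE], C)
      expect_equal(uni$t[j]^2, f1$F, tolerance = 1e-8)
      expect_equal(uni$p[j], f1$p, tolerance = 1e-8)
    }
    # and against lm() as an independent route
    fit <- lm(ph$phenotype ~ g$dosages[, 3] + C)
    expect_equal(uni$beta[3], unname(coef(fit)[2]), tolerance = 1e-10)
  })
})

test_that("gene_min_p reduces to the SNP p-value for single-SNP genes", {
  withr::with_seed(213, {
    g <- toy_gene(n = 60, m = 3, seed = 77)
    ph <- tibble::tibble(
      subject_id = subject_ids(g), phenotype = rnorm(60)
    )
    uni <- univariate_scan(g, ph)
    map <- gene_map(data.frame(
      snp_id = g$snps$snp_id, gene_id = c("g1", "g1", "g2")
    ))
    mp <- gene_min_p(uni, map)
    expect_equal(mp$min_p[mp$gene_id == "g2"], uni$p[3])
    expect_equal(mp$min_p[mp$gene_id == "g1"], min(uni$p[1:2]))
  })
})

test_that("gene_scan tests every gene, sorts by p and flags significance", {
  cfg <- sim_config(
    n_subjects = 250,
    genes = setNames(rep(6L, 8), sprintf("g%02d", 1:8)),
    causal = data.frame(
      gene_id = "g03", snp_index = 1:3, effect = 0.5
    ),
    seed = 53
  )
  co <- simulate_cohort(cfg)
  res <- gene_scan(co$genotypes, co$gene_map, co$phenotypes,
    covariates = c("age", "sex")
  )
  expect_s3_class(res, "gene_scan")
  expect_equal(nrow(res), 8)
  expect_equal(res$gene_id[1], "g03")
  expect_false(is.unsorted(res$p))
  expect_true(res$significant[1])
  expect_equal(attr(res, "threshold"), 0.05 / 8)
  # df bookkeeping: df2 = N - (covariates + intercept) - df1
  expect_equal(res$df2, 250L - 3L - res$df1)
  # empty selections carry p = 1 by convention
  expect_true(all(res$p[res$n_snps_selected == 0] == 1))
  gl <- glance(res)
  expect_equal(gl$top_gene, "g03")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("gene_scan is deterministic and respects external gene counts", {
  cfg <- sim_config(
    n_subjects = 120, genes = c(gA = 4, gB = 4), seed = 61
  )
  co <- simulate_cohort(cfg)
  r1 <- gene_scan(co$genotypes, co$gene_map, co$phenotypes,
    n_genes = 18284
  )
  r2 <- gene_scan(co$genotypes, co$gene_map, co$phenotypes,
    n_genes = 18284
  )
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_equal(attr(r1, "threshold"), 0.05 / 18284)
})

test_that("a gene of constant SNPs yields an empty selection and p = 1", {
  d <- cbind(a = rep(1, 50), b = rep(0, 50), c = rbinom(50, 2, 0.3))
  rownames(d) <- sprintf("s%02d", 1:50)
  g <- genotype_matrix(d)
  ph <- tibble::tibble(subject_id = rownames(d), phenotype = rnorm(50))
  map <- gene_map(data.frame(
    snp_id = c("a", "b", "c"), gene_id = c("gX", "gX", "gY")
  ))
  res <- suppressMessages(gene_scan(g, map, ph))
  row <- res[res$gene_id == "gX", ]
  expect_equal(row$n_snps_selected, 0L)
  expect_equal(row$p, 1)
})

test_that("nested CV schemes are seed-reproducible and keep strong signals", {
  cfg <- sim_config(
    n_subjects = 200, genes = c(gA = 4),
    causal = data.frame(gene_id = "gA", snp_index = 1, effect = 2.0),
    noise_sd = 0.1, age_beta = 0, sex_beta = 0, seed = 71
  )
  co <- simulate_cohort(cfg)
  r1 <- nested_cv_scan(co$genotypes, co$gene_map, co$phenotypes,
    scheme = "half_split", n_trials = 4, seed = 5
  )
  r2 <- nested_cv_scan(co$genotypes, co$gene_map, co$phenotypes,
    scheme = "half_split", n_trials = 4, seed = 5
  )
  expect_identical(r1, r2)
  expect_lt(r1$p_avg[1], 1e-6)
  r5 <- nested_cv_scan(co$genotypes, co$gene_map, co$phenotypes,
    scheme = "fifth_folds", seed = 5
  )
  expect_lt(r5$p_avg[1], 1e-6)
})

test_that("nested CV p-values are stochastically larger than in-sample ones", {
  # selection instability under the null: out-of-sample testing loses the
  # optimistic bias of selecting and testing on the same subjects
  res <- vapply(1:15, function(i) {
    cfg <- sim_config(
      n_subjects = 100, genes = c(gA = 8), age_beta = 0, sex_beta = 0,
      seed = 900 + i
    )
    co <- simulate_cohort(cfg)
    in_sample <- gene_scan(co$genotypes, co$gene_map, co$phenotypes)
    nested <- nested_cv_scan(co$genotypes, co$gene_map, co$phenotypes,
      scheme = "half_split", n_trials = 3, seed = i
    )
    c(nested$p_avg[1], in_sample$p[1], in_sample$n_snps_selected[1])
  }, numeric(3))
  # compare where the in-sample scan actually selected SNPs (an empty
  # selection already reports the maximal p = 1, leaving nothing to lose)
  sel <- res[3, ] > 0
  expect_gte(sum(sel), 3)
  expect_gt(mean(res[1, sel] > res[2, sel]), 0.5)
})
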