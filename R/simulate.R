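#' Simulation configuration
#'
#' Describes a synthetic cohort with the statistical structure the
#' gene-based scan assumes: LD-block-structured common variants grouped into
#' genes, a small set of causal SNPs with additive effects on a quantitative
#' trait, age/sex-like covariates, optional family relatedness (siblings or
#' monozygotic twins with a shared polygenic term), and an optional voxel
#' map carrying the genetic effect on a contiguous footprint.
#'
#' Within each gene the two haplotypes of every subject are independent
#' AR(1)-correlated latent Gaussians thresholded at each SNP's target minor
#' allele frequency, so Hardy-Weinberg equilibrium holds by construction;
#' the `inbreeding_f` knob duplicates a subject's second haplotype with the
#' given probability, creating the excess homozygosity needed to exercise
#' the HWE filter. Genes are independent blocks (no inter-gene LD).
#'
#' @param n_subjects Number of unrelated subjects (ignored when
#'   `n_families > 0`).
#' @param genes Named integer vector: gene id -> number of SNPs.
#' @param maf_range Range the per-SNP target minor allele frequencies are
#'   drawn from, a subset of (0, 0.5].
#' @param ld_rho Within-gene AR(1) correlation of the latent haplotype
#'   Gaussians, in [0, 1).
#' @param causal Data frame with columns `gene_id`, `snp_index`, `effect`
#'   (effect per standard deviation of dosage, in phenotype-noise-sd units),
#'   or `NULL` for a fully null trait.
#' @param age_beta,sex_beta Covariate effects (on standardized age and on
#'   the 0/1 sex indicator).
#' @param noise_sd Residual standard deviation of the trait.
#' @param polygenic_sd Standard deviation of a polygenic random effect with
#'   covariance `polygenic_sd^2 * K` (requires families; 0 disables).
#' @param n_families,family_size Family structure: `n_families` sibships of
#'   `family_size` full siblings (total subjects
#'   `n_families * family_size`).
#' @param mz Make each family a monozygotic twin pair (forces
#'   `family_size = 2`; genotypes duplicated, kinship entry 1).
#' @param inbreeding_f Per-subject probability of duplicating the second
#'   haplotype (creates HWE violations; default 0).
#' @param n_voxels Number of voxel phenotype columns (0 disables the map).
#' @param voxel_footprint Number of leading (contiguous) voxels carrying the
#'   genetic signal.
#' @param seed Integer seed; mandatory, every simulation is deterministic
#'   given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 300,
                       genes = setNames(rep(10L, 20), sprintf("g%02d", 1:20)),
                       maf_range = c(0.15, 0.45), ld_rho = 0.5,
                       causal = NULL, age_beta = 0.05, sex_beta = 0.3,
                       noise_sd = 1, polygenic_sd = 0,
                       n_families = 0, family_size = 2, mz = FALSE,
                       inbreeding_f = 0, n_voxels = 0, voxel_footprint = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must be within (0, 0.5] and increasing")
  }
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must be in [0, 1)")
  if (is.null(names(genes)) || any(genes < 1)) {
    abort("genes must be a named vector of positive SNP counts")
  }
  if (!is.null(causal)) {
    causal <- tibble::as_tibble(causal)
    stopifnot(all(c("gene_id", "snp_index", "effect") %in% names(causal)))
    bad <- !causal$gene_id %in% names(genes) |
      causal$snp_index > genes[causal$gene_id]
    if (any(bad)) abort("causal entries refer to SNPs outside the configured genes")
  }
  if (mz) family_size <- 2L
  structure(list(
    n_subjects = as.integer(n_subjects), genes = genes,
    maf_range = maf_range, ld_rho = ld_rho, causal = causal,
    age_beta = age_beta, sex_beta = sex_beta, noise_sd = noise_sd,
    polygenic_sd = polygenic_sd, n_families = as.integer(n_families),
    family_size = as.integer(family_size), mz = mz,
    inbreeding_f = inbreeding_f, n_voxels = as.integer(n_voxels),
    voxel_footprint = as.integer(voxel_footprint), seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects, %d genes (%d SNPs), seed %d\n",
    if (x$n_families > 0) x$n_families * x$family_size else x$n_subjects,
    length(x$genes), sum(x$genes), x$seed
  ))
  invisible(x)
}

#' Gene map implied by a simulation configuration
#' @param config A [sim_config()].
#' @return A `gene_map` tibble covering every simulated SNP.
#' @export
sim_gene_map <- function(config) {
  pairs <- purrr::imap(config$genes, function(m, gid) {
    tibble::tibble(snp_id = sprintf("%s_s%02d", gid, seq_len(m)), gene_id = gid)
  })
  gene_map(dplyr::bind_rows(pairs))
}

# One haplotype block for a gene: N x m 0/1 matrix, AR(1) latent Gaussian
# thresholded at each SNP's target MAF.
sim_haplotype <- function(n, mafs, rho) {
  m <- length(mafs)
  z <- matrix(rnorm(n * m), n, m)
  if (m > 1 && rho > 0) {
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  # carrier of the minor allele when the latent value is in the lower tail
  z < matrix(qnorm(mafs), n, m, byrow = TRUE)
}

# Draw per-SNP target MAFs for every gene (deterministic under the caller's
# seed discipline).
sim_target_mafs <- function(config) {
  lapply(config$genes, function(m) {
    runif(m, config$maf_range[1], config$maf_range[2])
  })
}

sim_snp_meta <- function(config) {
  rows <- purrr::imap(config$genes, function(m, gid) {
    tibble::tibble(
      snp_id = sprintf("%s_s%02d", gid, seq_len(m)),
      chrom = gid, pos = seq_len(m) * 1000L,
      ref = "A", alt = "B"
    )
  })
  dplyr::bind_rows(rows[names(config$genes)])
}

#' Simulate LD-block-structured genotypes for unrelated subjects
#'
#' See [sim_config()] for the generative model. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  withr::with_seed(config$seed, {
    n <- config$n_subjects
    mafs <- sim_target_mafs(config)
    blocks <- lapply(names(config$genes), function(gid) {
      h1 <- sim_haplotype(n, mafs[[gid]], config$ld_rho)
      h2 <- sim_haplotype(n, mafs[[gid]], config$ld_rho)
      if (config$inbreeding_f > 0) {
        dup <- runif(n) < config$inbreeding_f
        h2[dup, ] <- h1[dup, , drop = FALSE]
      }
      h1 + h2
    })
    d <- do.call(cbind, blocks)
    storage.mode(d) <- "double"
    rownames(d) <- sprintf("sub%04d", seq_len(n))
    genotype_matrix(d, snps = sim_snp_meta(config))
  })
}

#' Simulate families of siblings or MZ twins, with the pedigree kinship
#'
#' Each family draws two parents' haplotypes per gene; each sibling inherits
#' one haplotype from each parent (whole-gene transmission, no
#' recombination), giving an expected additive relationship of 0.5 between
#' full siblings. The `mz` option duplicates the first twin's genotypes
#' (relationship 1). The returned kinship matrix is the true pedigree
#' relationship matrix (block-diagonal; unrelated pairs exactly 0).
#'
#' @param config A [sim_config()] with `n_families > 0`.
#' @return List: `genotypes` (a [genotype_matrix()]) and `kinship`
#'   (subject-aligned matrix).
#' @export
simulate_families <- function(config) {
  if (config$n_families < 1) abort("n_families must be >= 1")
  withr::with_seed(config$seed + 2L, {
    fs <- config$family_size
    nf <- config$n_families
    n <- nf * fs
    mafs <- sim_target_mafs(config)
    blocks <- lapply(names(config$genes), function(gid) {
      m <- config$genes[[gid]]
      d <- matrix(0, n, m)
      for (f in seq_len(nf)) {
        par_h <- lapply(1:4, function(i) sim_haplotype(1, mafs[[gid]], config$ld_rho))
        rows <- (f - 1) * fs + seq_len(fs)
        for (s in seq_len(fs)) {
          if (config$mz && s == 2) {
            d[rows[2], ] <- d[rows[1], ]
          } else {
            mat_h <- par_h[[sample.int(2, 1)]]
            pat_h <- par_h[[2 + sample.int(2, 1)]]
            d[rows[s], ] <- mat_h + pat_h
          }
        }
      }
      d
    })
    d <- do.call(cbind, blocks)
    storage.mode(d) <- "double"
    rownames(d) <- sprintf("sub%04d", seq_len(n))
    g <- genotype_matrix(d, snps = sim_snp_meta(config))
    rel <- if (config$mz) 1 else 0.5
    blockK <- matrix(rel, fs, fs)
    diag(blockK) <- 1
    K <- kronecker(diag(nf), blockK)
    dimnames(K) <- list(rownames(d), rownames(d))
    list(genotypes = g, kinship = K)
  })
}

#' Simulate a quantitative phenotype (and optional voxel map)
#'
#' `y = sum(effect_j * standardized dosage_j) + age_beta * age_std +
#' sex_beta * sex + polygenic + noise`, with the polygenic term drawn with
#' covariance `polygenic_sd^2 * K` when a kinship matrix is supplied. When
#' `n_voxels > 0`, a subject-by-voxel matrix is attached as attribute
#' `"voxel_map"`: the leading `voxel_footprint` voxels carry the same
#' genetic (and covariate) signal with voxel-independent noise, the
#' remaining voxels carry covariates and noise only.
#'
#' @param g A [genotype_matrix()] produced under the same `config`.
#' @param config A [sim_config()].
#' @param K Optional kinship matrix (required when `polygenic_sd > 0`).
#' @return Tibble: `subject_id`, `phenotype`, `age`, `sex`; attribute
#'   `voxel_map` when configured.
#' @export
simulate_phenotype <- function(g, config, K = NULL) {
  withr::with_seed(config$seed + 1L, {
    n <- nrow(g$dosages)
    age <- rnorm(n, 60, 10)
    sex <- rbinom(n, 1, 0.5)
    genetic <- numeric(n)
    if (!is.null(config$causal)) {
      for (i in seq_len(nrow(config$causal))) {
        sid <- sprintf(
          "%s_s%02d", config$causal$gene_id[i], config$causal$snp_index[i]
        )
        if (!sid %in% colnames(g$dosages)) {
          abort(paste0("causal SNP not present in genotypes: ", sid))
        }
        x <- g$dosages[, sid]
        if (sd(x) > 0) {
          genetic <- genetic + config$causal$effect[i] * as.numeric(scale(x))
        }
      }
    }
    poly <- numeric(n)
    if (config$polygenic_sd > 0) {
      if (is.null(K)) abort("polygenic_sd > 0 requires a kinship matrix")
      ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
      L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
      poly <- config$polygenic_sd * as.numeric(L %*% rnorm(n))
    }
    fixed <- config$age_beta * as.numeric(scale(age)) + config$sex_beta * sex
    y <- genetic + poly + fixed + rnorm(n, 0, config$noise_sd)
    out <- tibble::tibble(
      subject_id = rownames(g$dosages), phenotype = y, age = age, sex = sex
    )
    if (config$n_voxels > 0) {
      V <- config$n_voxels
      fp <- min(config$voxel_footprint, V)
      vox <- matrix(rnorm(n * V, 0, config$noise_sd), n, V)
      vox <- vox + fixed # covariate signal everywhere
      if (fp > 0) {
        vox[, seq_len(fp)] <- vox[, seq_len(fp), drop = FALSE] + genetic + poly
      }
      dimnames(vox) <- list(rownames(g$dosages), sprintf("v%03d", seq_len(V)))
      attr(out, "voxel_map") <- vox
    }
    out
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper producing genotypes (with families and kinship when
#' configured), the gene map, the phenotype table and the optional voxel
#' map, all from one [sim_config()].
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `genotypes`, `phenotypes`,
#'   `gene_map`, `kinship` (`NULL` for unrelated designs), `voxel_map`
#'   (`NULL` unless configured), `config`.
#' @export
simulate_cohort <- function(config) {
  if (config$n_families > 0) {
    fam <- simulate_families(config)
    g <- fam$genotypes
    K <- fam$kinship
  } else {
    g <- simulate_genotypes(config)
    K <- NULL
  }
  ph <- simulate_phenotype(g, config, K = K)
  structure(list(
    genotypes = g, phenotypes = ph, gene_map = sim_gene_map(config),
    kinship = K, voxel_map = attr(ph, "voxel_map"), config = config
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d subjects, %d genes, kinship: %s, voxels: %d\n",
    nrow(x$genotypes$dosages), length(x$config$genes),
    ifelse(is.null(x$kinship), "none", "pedigree"),
    ifelse(is.null(x$voxel_map), 0L, ncol(x$voxel_map))
  ))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the dosage table, gene map, phenotype table, and (when present)
#' voxel map and kinship matrix, plus the configuration as JSON, into a
#' directory.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    config = file.path(dir, "config.json")
  )
  write_genotypes(sim$genotypes, paths[["genotypes"]])
  write_gene_map(sim$gene_map, paths[["gene_map"]])
  readr::write_tsv(sim$phenotypes, paths[["phenotypes"]], progress = FALSE)
  cfg <- sim$config
  cfg$genes <- as.list(cfg$genes)
  jsonlite::write_json(unclass(cfg), paths[["config"]],
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  if (!is.null(sim$voxel_map)) {
    paths[["voxels"]] <- file.path(dir, "voxels.tsv")
    vox <- dplyr::bind_cols(
      tibble::tibble(subject_id = rownames(sim$voxel_map)),
      tibble::as_tibble(sim$voxel_map)
    )
    readr::write_tsv(vox, paths[["voxels"]], progress = FALSE)
  }
  if (!is.null(sim$kinship)) {
    paths[["kinship"]] <- file.path(dir, "kinship.tsv")
    write_kinship(sim$kinship, paths[["kinship"]])
  }
  invisible(paths)
}
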