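---
title: "Gene-based SNP-set association with LASSO selection and partial F-tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based SNP-set association with LASSO selection and partial F-tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefscan)
```

## The model

Single-SNP genome-wide scans of a quantitative endophenotype (for example a
template-space temporal-lobe volume from tensor-based morphometry) test each
common variant in isolation and pay a per-SNP multiple-testing price. When
several variants inside one gene each carry a modest additive signal,
aggregating them can detect the gene where no single SNP reaches
significance. `genefscan` implements that gene-centric strategy in two
stages, per gene:

1. **Sparse selection.** With the phenotype residualized on the covariates
   (age, sex, ancestry components), the gene's dosage columns enter an
   L1-penalized least-squares fit
   $$\beta^{*} = \arg\min_\beta \tfrac{1}{2N}\lVert y - X\beta\rVert_2^2
     + \lambda \lVert\beta\rVert_1,$$
   solved by cyclic coordinate descent over a warm-started, log-spaced
   penalty path. The penalty $\lambda$ is chosen by leave-one-out
   cross-validation under the mean-squared-error criterion; ties go to the
   larger penalty (the sparser model). The SNPs with nonzero coefficients
   form the gene's selected subset. The LASSO is used **only as a filter**:
   its coefficients are discarded.
2. **Joint testing.** The selected dosages join the covariates in an
   ordinary linear model, and a partial F-test compares it to the
   covariates-only reduced model:
   $$F = \frac{(\mathrm{RSS}_{\text{reduced}} - \mathrm{RSS}_{\text{full}})/d_1}
             {\mathrm{RSS}_{\text{full}}/d_2},$$
   with $d_1$ the rank of the selected block after projecting out the
   covariates and $d_2 = N - c - d_1$ ($c$ counts covariates plus
   intercept). Gene-level significance uses a Bonferroni threshold
   $\alpha / n_{\text{genes}}$; for a genome-wide scan of 18,284 genes at
   $\alpha = 0.05$ that is $2.73\times 10^{-6}$.

An empty selection reports $p = 1$ rather than skipping the gene: skipping
would silently shrink the Bonferroni denominator.

For related samples (twin/sibling cohorts) the same contrast is run as a
mixed model: $y \sim N(Xb,\ \sigma_g^2 K + \sigma_e^2 I)$ with $K$ a kinship
(relationship) matrix. Variance components are estimated once by REML under
the reduced model on eigen-rotated data, all design blocks are whitened
through the eigenbasis of $K$, and the ordinary partial-F machinery applies
to the whitened data — the single-estimation ("EMMAX-style") approximation
that makes genome-wide scans tractable. With $K = I$ this reduces exactly
to the ordinary test.

Post-hoc, the fixed selected SNP set can be tested against every column of
a subject-by-voxel phenotype matrix (`voxelwise_f_map()`), with
Benjamini–Hochberg step-up control of the false discovery rate over voxels
(`bh_fdr()`) and mask comparison across cohorts (`map_overlap()`).

## Assumptions

* Additive minor-allele coding (0/1/2; fractional imputed dosages allowed).
* Common variants: the default QC keeps MAF strictly greater than 0.1 and
  excludes SNPs whose exact Hardy–Weinberg p-value falls below
  $5.7\times10^{-7}$. The HWE threshold targets a deep tail, which is why
  the test is the exact (enumeration-based) one rather than chi-square.
* Phenotype and covariates complete after the cohort join; subjects with
  missing values are dropped with a reported count.
* The primary scan assumes unrelated subjects; the mixed-model variant
  handles relatedness through $K$.

Selection and testing share the same subjects in the primary scan; the
resulting p-values are post-selection quantities, calibrated here (as in
the method's own usage) empirically. `nested_cv_scan()` provides the honest
variants — selection on a fifth and testing on the rest, or random
half-splits averaged over trials — which cost power but remove the reuse.
The package implements both and does not adjudicate between them.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `maf_threshold` | `apply_qc()` | 0.1 (strict `>`) | common-variant design; small samples cannot resolve rarer effects |
| `hwe_threshold` | `apply_qc()` | 5.7e-7 | conventional genotyping-artifact filter at genome-wide scale |
| `n_folds` | `select_snps()` | `NULL` = leave-one-out | deterministic CV, the scheme the method was designed with |
| `n_lambda`, `lambda_min_ratio` | `lambda_path()` | 100, 1e-3 | standard path span; first point is exactly the all-zero model |
| `tol`, `max_iter` | `lasso_fit()` | 1e-7, 10,000 | convergence on max coefficient change; KKT residual attached |
| `alpha`, `n_genes` | `gene_scan()` | 0.05, genes tested | use the genome-wide gene count when scanning a subset |
| `q` | `bh_fdr()` | 0.05 | target FDR over voxels |
| `k` | `genotype_pcs()` | 4 | ancestry components standing in for MDS parameters |

## Numerical choices

* The L1 objective carries a $1/(2N)$ loss factor (the parameterization of
  the standard coordinate-descent software), so $\lambda$ is comparable
  across sample sizes. $\lambda$ values are internal and never reported as
  scientific output.
* Genotype columns are standardized before fitting and coefficients
  back-transformed to the dosage scale; the response is centered, and CV
  folds re-center using training-fold means only.
* Exactly duplicated standardized columns are removed before fitting, the
  lowest column index kept. With exact duplicates the L1 solution splits
  weight arbitrarily, and warm starts along the path let a duplicate retain
  real weight, so deduplication is the only way to make the documented
  lowest-index tie-break exact.
* Standardized-scale coefficients smaller than 1e-9 after the path fit are
  treated as exact zeros (the convergence tolerance is 1e-7; anything below
  it is unresolved noise).
* Rank of the selected block is judged against the *original* block's
  column norms, so a block annihilated by the covariate projection counts
  as fully aliased ($d_1 = 0$, $p = 1$). Aliased columns drop in column
  order.
* A perfectly fitting full model ($\mathrm{RSS}_{\text{full}} = 0$) floors
  the p-value at the smallest positive double and warns, rather than
  returning 0.
* REML maximizes over $\delta = \sigma_e^2/\sigma_g^2$ on a 100-point
  log-grid spanning $[10^{-5}, 10^5]$ with local refinement; a maximum on
  the upper bound (flat likelihood, $\sigma_g^2 \to 0$) warns and
  degenerates to the ordinary test. With $K = I$ the restricted likelihood
  is constant in $\delta$; any value whitens to the same F, which is the
  behavior the tests pin down.
* Scaling $K$ by $c$ rescales $\hat\delta$ by $c$ and leaves F unchanged.

## What the simulator emulates — and what it does not

`sim_config()` + `simulate_cohort()` generate the data regime the method
assumes: genes as independent LD blocks (within-gene AR(1) latent-Gaussian
haplotypes, one correlation knob `ld_rho`), common variants with target
MAFs drawn from (0.15, 0.45) — comfortably inside the MAF > 0.1 filter —
additive effects on a quantitative trait in noise-sd units, age/sex-like
covariates, optional sibships or MZ twin pairs with the true pedigree
relationship matrix and a shared polygenic term, and optional voxel maps
carrying the genetic signal on a contiguous footprint. Haplotypes are
independent, so Hardy–Weinberg holds by construction; an `inbreeding_f`
knob duplicates haplotypes to create the excess homozygosity needed to
exercise the HWE filter.

Not emulated: coalescent realism, recombination within genes, inter-gene
LD, population stratification, genotyping error, and the spatial
autocorrelation of real imaging phenotypes. Passing tests therefore show
the machinery is correct and calibrated under the assumed regime, not that
the method is robust to the full messiness of real cohorts — in particular
the BH-over-voxels step treats voxels as exchangeable, where real maps are
smooth.

## Study sizes used by the test and acceptance suites

These sizes are the package's own choices for a desk-scale demonstration:
boost of joint over single-SNP testing — one gene of 10 SNPs with 3 causal
at 0.4 sd, N = 500, 100 replicates; end-to-end detection — 10 genes × 8
SNPs, N = 300, 3 causal SNPs at 0.5 sd, judged at the genome-wide
2.73e-6 threshold over 20 replicates; mixed-model calibration — 100 sib
pairs, polygenic sd 1.5 vs noise sd 1 (familial resemblance ≈ 0.35 between
sibs), 1000 replicates; FDR control — 200 null maps of 100 voxels. The
suites compute every number they assert at run time.

## Worked example

```{r, eval = FALSE}
library(genefscan)

cfg <- sim_config(
  n_subjects = 300,
  genes = setNames(rep(8L, 10), sprintf("g%02d", 1:10)),
  causal = data.frame(gene_id = "g05", snp_index = c(1, 4, 7), effect = 0.5),
  seed = 42
)
co <- simulate_cohort(cfg)

qc <- apply_qc(co$genotypes)
scan <- gene_scan(qc$genotypes, co$gene_map, co$phenotypes,
  covariates = c("age", "sex"), n_genes = 18284
)
glance(scan)
autoplot(scan)

# single-SNP baseline and the per-gene minimum p
uni <- univariate_scan(qc$genotypes, co$phenotypes, covariates = c("age", "sex"))
gene_min_p(uni, co$gene_map)
```

## Known limitations

* In-sample select-then-test p-values are optimistic by construction; use
  `nested_cv_scan()` when honesty matters more than power.
* One variance-component, one kinship matrix; no dominance or multiple
  random effects.
* BH is the only FDR dialect; spatially-informed (regional) FDR is not
  implemented.
* Mean imputation of missing dosages is a desk-scale stand-in for proper
  haplotype-based imputation.
* SNPs overlapping several genes are assigned to the lexicographically
  first gene so gene tests stay structurally disjoint; with real
  annotation this choice is arbitrary and worth revisiting.
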