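test_that("nominal scan matches the closed-form simple regression", {
  y <- c(1, 2, 3, 4, 5)
  g <- c(0, 0, 1, 1, 2)
  ex <- toy_expression(matrix(y, nrow = 1), chrom = 2L, tss = 1000L)
  gt <- toy_genotypes(matrix(g, ncol = 1), chrom = 1L, pos = 500L)
  rec <- nominal_scan(ex, gt, mode = "trans")
  oracle <- hand_ols(y, g)
  expect_equal(rec$beta, oracle$beta, tolerance = 1e-12)
  expect_equal(rec$se, oracle$se, tolerance = 1e-12)
  expect_equal(rec$p, oracle$p, tolerance = 1e-12)
  expect_equal(rec$df, oracle$df)
  # consistency invariant: p reproduces t = beta/se at df
  expect_equal(rec$p, 2 * pt(-abs(rec$beta / rec$se), rec$df), tolerance = 1e-8)
})

test_that("scan agrees with lm() in the presence of covariates", {
  set.seed(8)
  n <- 50
  g <- rbinom(n, 2, 0.4)
  x1 <- rnorm(n)
  y <- 0.4 * g + 0.8 * x1 + rnorm(n)
  ex <- toy_expression(matrix(y, nrow = 1), chrom = 2L, tss = 1000L)
  gt <- toy_genotypes(matrix(as.numeric(g), ncol = 1), chrom = 1L, pos = 500L)
  cv <- structure(scale(matrix(x1, ncol = 1), scale = FALSE),
                  class = c("covariate_matrix", "matrix", "array"))
  rownames(cv) <- colnames(ex$values)
  colnames(cv) <- "x1"
  rec <- nominal_scan(ex, gt, cv, mode = "trans")
  fit <- summary(lm(y ~ g + x1))$coefficients
  expect_equal(rec$beta, fit["g", "Estimate"], tolerance = 1e-10)
  expect_equal(rec$se, fit["g", "Std. Error"], tolerance = 1e-10)
  expect_equal(rec$p, fit["g", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("the trans window excludes near-TSS pairs and cis includes them", {
  set.seed(2)
  g <- matrix(as.numeric(rbinom(20 * 3, 2, 0.3)), ncol = 3)
  gt <- toy_genotypes(g, chrom = c(1L, 1L, 2L),
                      pos = c(4900000L, 6000000L, 100L))
  ex <- toy_expression(matrix(rnorm(20), nrow = 1), chrom = 1L, tss = 0L)
  trans <- nominal_scan(ex, gt, mode = "trans")
  # 4.9 Mb same-chrom variant falls in neither window; 6 Mb and other-chrom do
  expect_setequal(trans$variant_id, c("v02", "v03"))
  cis <- nominal_scan(ex, gt, mode = "cis")
  expect_equal(nrow(cis), 0L) # nearest variant is 4.9 Mb away, past the 1 Mb window

  ex2 <- toy_expression(matrix(rnorm(20), nrow = 1), chrom = 1L, tss = 4000000L)
  cis2 <- nominal_scan(ex2, gt, mode = "cis")
  expect_setequal(cis2$variant_id, "v01")
})

test_that("monomorphic variants are skipped with a message", {
  set.seed(5)
  g <- cbind(as.numeric(rbinom(30, 2, 0.4)), rep(1, 30))
  gt <- toy_genotypes(g, chrom = c(1L, 1L), pos = c(100L, 200L))
  ex <- toy_expression(matrix(rnorm(30), nrow = 1), chrom = 2L, tss = 0L)
  expect_message(rec <- nominal_scan(ex, gt, mode = "trans"), "monomorphic")
  expect_equal(rec$variant_id, "v01")
})

test_that("cross-mappability filtering removes exactly the blacklisted pairs", {
  recs <- tibble::tibble(
    variant_id = paste0("v", 1:10), gene_id = paste0("g", 1:10),
    p = seq(0.01, 0.1, by = 0.01)
  )
  bl <- tibble::tibble(locus_a = c("g1", "v5", "v7"),
                       locus_b = c("v1", "g5", "g7"))
  expect_message(out <- cross_map_filter(recs, bl), "removed 3")
  expect_equal(nrow(out), 7L)
  expect_false(any(out$variant_id %in% c("v1", "v5", "v7")))
  expect_identical(cross_map_filter(recs, bl[0, ]), recs)
})

test_that("greedy LD pruning keeps the hand-traced independent set", {
  # exact-correlation construction: A-B and B-C dependent, A-C independent
  m <- correlated_triplet(sqrt(0.65), sqrt(0.65), sqrt(0.3))
  colnames(m) <- c("vA", "vB", "vC")
  gt <- toy_genotypes(m, chrom = rep(1L, 3), pos = c(100L, 200L, 300L))
  r2 <- cor(m)^2
  expect_equal(unname(r2[1, 2]), 0.65, tolerance = 1e-9)
  expect_equal(unname(r2[2, 3]), 0.65, tolerance = 1e-9)
  expect_equal(unname(r2[1, 3]), 0.3, tolerance = 1e-9)
  recs <- tibble::tibble(variant_id = c("vA", "vB", "vC"), gene_id = "g1",
                         p = c(1e-8, 1e-6, 1e-4))
  kept <- ld_prune(recs, gt, r2_threshold = 0.6)
  expect_setequal(kept$variant_id, c("vA", "vC"))

  # duplicate-variant records: smaller p wins under global pruning
  m2 <- cbind(vX = m[, 1], vY = m[, 1])
  gt2 <- toy_genotypes(m2, chrom = c(1L, 1L), pos = c(100L, 200L))
  recs2 <- tibble::tibble(variant_id = c("vX", "vY"), gene_id = "g1",
                          p = c(0.01, 0.001))
  kept2 <- ld_prune(recs2, gt2, r2_threshold = 0.6)
  expect_equal(kept2$variant_id, "vY")

  # independent variants all survive
  set.seed(9)
  m3 <- matrix(as.numeric(rbinom(600, 2, 0.4)), ncol = 3)
  gt3 <- toy_genotypes(m3, chrom = rep(1L, 3), pos = c(1L, 2L, 3L) * 100L)
  recs3 <- tibble::tibble(variant_id = colnames(gt3$dosage), gene_id = "g1",
                          p = c(0.1, 0.2, 0.3))
  expect_equal(nrow(ld_prune(recs3, gt3, 0.6)), 3L)
})

test_that("per-gene pruning leaves one variant serving several genes", {
  m <- correlated_triplet(sqrt(0.9), sqrt(0.9), sqrt(0.9))
  colnames(m) <- c("v1", "v2", "v3")
  gt <- toy_genotypes(m, chrom = rep(1L, 3), pos = c(100L, 200L, 300L))
  recs <- tibble::tibble(
    variant_id = rep(c("v1", "v2", "v3"), times = 3),
    gene_id = rep(c("gA", "gB", "gC"), each = 3),
    p = c(1e-9, 1e-5, 1e-4, 1e-8, 1e-6, 1e-3, 1e-7, 1e-5, 1e-2)
  )
  kept <- ld_prune(recs, gt, r2_threshold = 0.6)
  expect_equal(nrow(kept), 3L)                 # one record per gene
  expect_setequal(unique(kept$variant_id), "v1") # same eSNP for all genes
  # invariant: kept records of one gene have pairwise r2 <= threshold
  for (g in unique(kept$gene_id)) {
    vs <- kept$variant_id[kept$gene_id == g]
    if (length(vs) > 1) {
      expect_lte(max(cor(gt$dosage[, vs])^2[upper.tri(diag(length(vs)))]), 0.6)
    }
  }
})

test_that("pooled BH selection matches brute-force BH", {
  recs <- tibble::tibble(variant_id = paste0("v", 1:4), gene_id = "g",
                         p = c(0.01, 0.02, 0.03, 0.04))
  out <- pooled_fdr(recs, alpha = 0.05)
  expect_equal(nrow(out), 4L)
  expect_equal(max(out$q), 0.04)
  # brute force: q_i = min over j >= i of m * p_(j) / j
  ps <- sort(recs$p)
  qs <- rev(cummin(rev(4 * ps / seq_len(4))))
  expect_equal(sort(out$q), qs)

  expect_equal(nrow(pooled_fdr(dplyr::mutate(recs, p = 1), 0.05)), 0L)
  one <- pooled_fdr(tibble::tibble(variant_id = "v", gene_id = "g", p = 0.2), 0.25)
  expect_equal(nrow(one), 1L)
  expect_equal(one$q, 0.2)
})

test_that("pooled FDR retention is monotone in alpha", {
  set.seed(14)
  recs <- tibble::tibble(variant_id = paste0("v", 1:200), gene_id = "g",
                         p = c(runif(20, 0, 1e-4), runif(180)))
  sizes <- vapply(c(1, 0.25, 0.05, 0.01),
                  function(a) nrow(pooled_fdr(recs, a)), numeric(1))
  expect_equal(sizes[1], 200) # alpha = 1 returns everything
  expect_true(all(diff(sizes) <= 0))
})

test_that("hierarchical gene-level correction applies Sidak then BH", {
  # single gene, single SNP reduces to q = p
  one <- hierarchical_gene_fdr(
    tibble::tibble(variant_id = "v", gene_id = "g", p = 0.03),
    c(g = 1), alpha = 0.25
  )
  expect_equal(one$p_corrected, 0.03)
  expect_equal(one$q, 0.03)

  # direct evaluation of 1 - (1 - p)^m
  two <- hierarchical_gene_fdr(
    tibble::tibble(variant_id = "v", gene_id = "g", p = 0.001),
    c(g = 100), alpha = 0.25
  )
  expect_equal(two$p_corrected, 1 - 0.999^100, tolerance = 1e-12)
  expect_equal(round(two$p_corrected, 4), 0.0952)

  # monotone in m at fixed p_min
  ms <- c(1, 5, 50, 500)
  corr <- vapply(ms, function(m) {
    hierarchical_gene_fdr(tibble::tibble(variant_id = "v", gene_id = "g", p = 0.001),
                          c(g = m), 0.25)$p_corrected
  }, numeric(1))
  expect_true(all(diff(corr) > 0))
})

test_that("permutation FDR flags a strong planted cis gene at the floor p", {
  cfg <- sim_config(n_samples = 300, n_chromosomes = 1,
                    n_variants_per_chrom = 20, n_genes_per_chrom = 5,
                    ld_block_size = 5, noise_sd = 0.5, n_hidden_factors = 0,
                    seed = 31,
                    effects = planted_effect("cis", "chr1_v0001", "g1_001", a = 2))
  co <- simulate_cohort(cfg)
  nx <- normalize_expression(co$expression)
  res <- permutation_gene_fdr(nx, co$genotypes, mode = "cis", n_perm = 1000,
                              alpha = 0.25, seed = 77)
  expect_equal(unname(res$genes$empirical_p[res$genes$gene_id == "g1_001"]),
               1 / 1001)
  expect_true("g1_001" %in% res$records$gene_id)
  # identical seed reproduces the result exactly
  res2 <- permutation_gene_fdr(nx, co$genotypes, mode = "cis", n_perm = 1000,
                               alpha = 0.25, seed = 77)
  expect_identical(res$genes, res2$genes)
  expect_identical(res$records, res2$records)
})

test_that("split-half folds are disjoint and duplicated data replicates fully", {
  # duplicated cohort: each sample appears once per fold by construction
  cfg <- sim_config(n_samples = 120, n_chromosomes = 2,
                    n_variants_per_chrom = 30, n_genes_per_chrom = 10,
                    ld_block_size = 5, n_hidden_factors = 0, seed = 41,
                    effects = dplyr::bind_rows(
                      planted_effect("cis", "chr1_v0001", "g1_001", a = 1),
                      planted_effect("direct_trans", "chr1_v0011",
                                     trans_gene_id = "g2_001", c = 1.5)
                    ))
  co <- simulate_cohort(cfg)
  dup_vals <- cbind(co$expression$values, co$expression$values)
  colnames(dup_vals) <- sprintf("s%04d", seq_len(240))
  dup_dos <- rbind(co$genotypes$dosage, co$genotypes$dosage)
  rownames(dup_dos) <- colnames(dup_vals)
  ex <- expression_matrix(dup_vals, co$expression$genes)
  gt <- genotype_matrix(dup_dos, co$genotypes$variants)
  nx <- normalize_expression(ex)
  # explicit folds carrying identical copies of the cohort
  out <- split_half_replication(nx, gt, alpha = 0.25,
                                folds = list(1:120, 121:240))
  expect_equal(out$overlap, 1)
  expect_gt(out$n_shared, 0)
  expect_error(split_half_replication(nx, gt, folds = list(1:120, 120:240)),
               "disjoint")
})

test_that("element enrichment reproduces the Fisher oracle", {
  # 2x2 of (8, 2, 10, 80): sample OR 32, p equals the hypergeometric sum
  variants <- tibble::tibble(
    variant_id = paste0("v", 1:100), chrom = 1L,
    pos = as.integer(c(seq_len(8) * 10L,      # v1..v8: inside (QTL)
                       1000L, 1010L,          # v9, v10: outside (QTL)
                       90L + seq_len(10) * 5L, # v11..v20: inside (background)
                       2000L + seq_len(80) * 10L))
  )
  qtl <- paste0("v", 1:10)
  el <- list(promoter = tibble::tibble(chrom = 1L, start = 0L, end = 185L))
  inside <- variants$pos < 185
  a <- sum(inside[1:10]); expect_equal(a, 8L)
  cc <- sum(inside[-(1:10)]); expect_equal(cc, 10L)
  res <- element_enrichment(variants, qtl, el)
  expect_equal(res$odds_ratio, 32)
  expect_equal(res$p, hypergeom_fisher_p(8, 2, 10, 80), tolerance = 1e-9)
  expect_equal(res$proportion, 0.8)

  # identical composition gives OR 1 and p 1
  el2 <- list(sym = tibble::tibble(chrom = 1L, start = 0L, end = 100L))
  v2 <- tibble::tibble(variant_id = paste0("w", 1:40), chrom = 1L,
                       pos = as.integer(rep(c(50L, 500L), 20)))
  res2 <- element_enrichment(v2, paste0("w", 1:10), el2)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)
})
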