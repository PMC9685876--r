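test_that("genotype simulation respects Hardy-Weinberg and MAF", {
  cfg <- sim_config(n_samples = 10000, n_chromosomes = 1,
                    n_variants_per_chrom = 1, maf_range = c(0.5, 0.5),
                    ld_block_size = 1, seed = 42)
  gt <- simulate_genotypes(cfg)
  # at MAF 0.5, mean dosage 1 with binomial(2, .5) sd per sample
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(gt$dosage) - 1), 3 * se)

  cfg2 <- sim_config(n_samples = 20000, n_chromosomes = 1,
                     n_variants_per_chrom = 10, maf_range = c(0.2, 0.2),
                     ld_block_size = 5, ld_within_block_r = 0.8, seed = 7)
  gt2 <- simulate_genotypes(cfg2)
  expect_true(all(abs(gt2$variants$maf - 0.2) < 0.01))
  expect_true(all(gt2$variants$maf > 0 & gt2$variants$maf <= 0.5))
})

test_that("MAF recovery tightens as the cohort grows", {
  err <- vapply(c(200, 20000), function(n) {
    cfg <- sim_config(n_samples = n, n_chromosomes = 1,
                      n_variants_per_chrom = 20, maf_range = c(0.3, 0.3),
                      ld_block_size = 1, seed = 5)
    mean(abs(simulate_genotypes(cfg)$variants$maf - 0.3))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("full within-block LD yields identical dosage columns", {
  cfg <- sim_config(n_samples = 50, n_chromosomes = 1,
                    n_variants_per_chrom = 6, ld_block_size = 3,
                    ld_within_block_r = 1, seed = 2)
  gt <- simulate_genotypes(cfg)
  expect_identical(gt$dosage[, 1], gt$dosage[, 2])
  expect_identical(gt$dosage[, 2], gt$dosage[, 3])
  expect_equal(cor(gt$dosage[, 1], gt$dosage[, 3])^2, 1)
})

test_that("within-block dosage correlation tracks the configured target", {
  cfg <- sim_config(n_samples = 20000, n_chromosomes = 1,
                    n_variants_per_chrom = 10, ld_block_size = 5,
                    ld_within_block_r = 0.8, seed = 9)
  gt <- simulate_genotypes(cfg)
  # configured value is the pairwise correlation, so r^2 targets 0.8^2
  r2 <- cor(gt$dosage[, 1], gt$dosage[, 2])^2
  expect_lt(abs(r2 - 0.8^2), 0.05)
  # across blocks: independent
  expect_lt(cor(gt$dosage[, 1], gt$dosage[, 6])^2, 0.01)
})

test_that("positions are strictly increasing within chromosome", {
  gt <- simulate_genotypes(sim_config(n_samples = 30, seed = 3))
  for (ch in unique(gt$variants$chrom)) {
    expect_true(all(diff(gt$variants$pos[gt$variants$chrom == ch]) > 0))
  }
})

test_that("noise-free cis effect reproduces dosage exactly", {
  cfg <- sim_config(n_samples = 40, n_chromosomes = 2,
                    n_variants_per_chrom = 10, n_genes_per_chrom = 5,
                    ld_block_size = 5, noise_sd = 0, n_hidden_factors = 0,
                    seed = 1,
                    effects = planted_effect("cis", "chr1_v0001", "g1_001", a = 1))
  gt <- simulate_genotypes(cfg)
  ex <- simulate_expression(gt, cfg)
  expect_equal(unname(ex$expression$values["g1_001", ]),
               unname(gt$dosage[, "chr1_v0001"]))
})

test_that("mediated path correlation matches the closed-form path coefficient", {
  eff <- dplyr::bind_rows(
    planted_effect("cis", "chr1_v0001", "g1_001", a = 1),
    planted_effect("mediated_trans", "chr1_v0001", "g1_001", "g1_002",
                   a = 1, b = 1, c = 0)
  )
  cfg <- sim_config(n_samples = 3000, n_chromosomes = 2,
                    n_variants_per_chrom = 10, n_genes_per_chrom = 5,
                    ld_block_size = 5, noise_sd = 0.1, n_hidden_factors = 0,
                    seed = 21, effects = eff)
  gt <- simulate_genotypes(cfg)
  ex <- simulate_expression(gt, cfg)
  g <- gt$dosage[, "chr1_v0001"]
  y_t <- ex$expression$values["g1_002", ]
  expected <- 1 * 1 * sd(g) / sd(y_t)
  expect_lt(abs(cor(g, y_t) - expected), 0.05)
})

test_that("a pure-null cohort shows null gene-variant correlations", {
  cfg <- sim_config(n_samples = 200, n_chromosomes = 2,
                    n_variants_per_chrom = 25, n_genes_per_chrom = 20,
                    ld_block_size = 5, n_hidden_factors = 0, seed = 13)
  gt <- simulate_genotypes(cfg)
  ex <- simulate_expression(gt, cfg)
  set.seed(1)
  cells <- sample(ncol(gt$dosage) * nrow(ex$expression$values), 1000)
  vi <- (cells - 1) %% ncol(gt$dosage) + 1
  gi <- (cells - 1) %/% ncol(gt$dosage) + 1
  r <- vapply(seq_len(1000), function(k) {
    cor(gt$dosage[, vi[k]], ex$expression$values[gi[k], ])
  }, numeric(1))
  # null correlation: t = r sqrt(df) / sqrt(1 - r^2) is t-distributed
  tval <- r * sqrt(198) / sqrt(1 - r^2)
  expect_gt(ks.test(pt(tval, 198), "punif")$p.value, 0.01)
})

test_that("regulatory truth is internally consistent", {
  cfg <- plant_architecture(sim_config(n_samples = 60, seed = 4),
                            n_cis = 3, n_mediated = 3, n_direct = 2,
                            n_hotspots = 2, targets_per_hotspot = 3)
  gt <- simulate_genotypes(cfg)
  truth <- simulate_expression(gt, cfg)$truth
  trans <- truth$effects[truth$effects$kind != "cis", ]
  for (v in truth$hotspot_variants) {
    expect_gte(length(unique(trans$trans_gene_id[trans$variant_id == v])), 3)
  }
  non_hot <- setdiff(unique(trans$variant_id), truth$hotspot_variants)
  for (v in non_hot) {
    expect_lt(length(unique(trans$trans_gene_id[trans$variant_id == v])), 3)
  }
  expect_true(all(truth$enriched_contact_pairs$chrom_a !=
                    truth$enriched_contact_pairs$chrom_b))
})

test_that("contact simulation plants the configured enrichment", {
  # large synthetic truth: enough enriched pairs for a law-of-large-numbers check
  cfg <- sim_config(n_samples = 10, n_chromosomes = 2, chrom_length_bp = 1e7,
                    n_variants_per_chrom = 10, n_genes_per_chrom = 5,
                    ld_block_size = 5, hic_baseline_mean = 5,
                    hic_enrichment_factor = 5, seed = 6)
  enriched <- tibble::tibble(
    chrom_a = 1L, bin_a = rep(0:99, each = 25),
    chrom_b = 2L, bin_b = rep(0:24, times = 100)
  )
  truth <- structure(list(enriched_contact_pairs = enriched),
                     class = "regulatory_truth")
  cm <- simulate_contact_matrix(truth, cfg)
  key <- paste(cm$chrom_a, cm$bin_a, cm$chrom_b, cm$bin_b)
  ekey <- paste(enriched$chrom_a, enriched$bin_a, enriched$chrom_b, enriched$bin_b)
  in_e <- key %in% ekey
  expect_lt(abs(mean(cm$freq[in_e]) / 5 - 5) / 5, 0.05)
  expect_lt(abs(mean(cm$freq[!in_e]) - 5) / 5, 0.05)
})

test_that("no enrichment factor means identical contact distributions", {
  cfg <- sim_config(n_samples = 10, n_chromosomes = 2, chrom_length_bp = 5e6,
                    n_variants_per_chrom = 10, n_genes_per_chrom = 5,
                    ld_block_size = 5, hic_enrichment_factor = 1, seed = 8)
  enriched <- tibble::tibble(chrom_a = 1L, bin_a = 0:24,
                             chrom_b = 2L, bin_b = 0:24)
  truth <- structure(list(enriched_contact_pairs = enriched),
                     class = "regulatory_truth")
  cm <- simulate_contact_matrix(truth, cfg)
  key <- paste(cm$chrom_a, cm$bin_a, cm$chrom_b, cm$bin_b)
  in_e <- key %in% paste(enriched$chrom_a, enriched$bin_a,
                         enriched$chrom_b, enriched$bin_b)
  expect_gt(wilcox.test(cm$freq[in_e], cm$freq[!in_e])$p.value, 0.01)
})

test_that("contact lookup is symmetric and binning is half-open", {
  cfg <- sim_config(n_samples = 10, n_chromosomes = 2, chrom_length_bp = 1e6,
                    n_variants_per_chrom = 5, n_genes_per_chrom = 2,
                    ld_block_size = 5, seed = 10)
  cm <- simulate_contact_matrix(NULL, cfg)
  expect_equal(contact_frequency(cm, 1, 3, 2, 5),
               contact_frequency(cm, 2, 5, 1, 3))
  expect_equal(map_to_bins(tibble::tibble(chrom = 1, pos = 250000), 100000)$bin, 2L)
  expect_equal(map_to_bins(tibble::tibble(chrom = 1, pos = c(0, 99999, 100000)),
                           100000)$bin, c(0L, 0L, 1L))
})

test_that("GWAS summaries are definitionally consistent and null-centred", {
  cfg <- sim_config(n_samples = 400, n_chromosomes = 2,
                    n_variants_per_chrom = 100, n_genes_per_chrom = 5,
                    seed = 12)
  gt <- simulate_genotypes(cfg)
  gw <- simulate_gwas_summary(gt, NULL, cfg)
  expect_equal(gw$p, 2 * pnorm(-abs(gw$beta / gw$se)), tolerance = 1e-6)
  z <- gw$beta / gw$se
  expect_lt(abs(mean(z)), 3 / sqrt(nrow(gw)))
})

test_that("a strongly planted GWAS causal variant wins its LD block", {
  cfg <- plant_architecture(
    sim_config(n_samples = 500, seed = 15, gwas_causal_z = 20),
    n_cis = 2, n_mediated = 3, n_direct = 2, n_hotspots = 1,
    n_gwas_causal = 3
  )
  gt <- simulate_genotypes(cfg)
  truth <- simulate_expression(gt, cfg)$truth
  gw <- simulate_gwas_summary(gt, truth, cfg)
  # ids encode the within-chromosome index, so block membership is arithmetic
  within_idx <- as.integer(sub(".*_v", "", gt$variants$variant_id))
  block_of <- (within_idx - 1L) %/% cfg$ld_block_size
  for (cv in truth$gwas_causal_variants) {
    i <- match(cv, gt$variants$variant_id)
    in_block <- gt$variants$chrom == gt$variants$chrom[i] &
      block_of == block_of[i]
    sub <- gw[gw$variant_id %in% gt$variants$variant_id[in_block], ]
    expect_equal(sub$variant_id[which.min(sub$p)], cv)
  }
})

test_that("the cohort generator is deterministic given config and seed", {
  cfg <- plant_architecture(
    sim_config(n_samples = 60, n_variants_per_chrom = 40,
               n_genes_per_chrom = 10, seed = 99),
    n_cis = 2, n_mediated = 2, n_direct = 1, n_hotspots = 1
  )
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(as.data.frame(a$contacts), as.data.frame(b$contacts))
  expect_identical(as.data.frame(a$gwas), as.data.frame(b$gwas))
})
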