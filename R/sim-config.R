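#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic genotype--expression--Hi-C--GWAS cohort:
#' cohort dimensions, the linkage-disequilibrium (LD) block model, the
#' hidden-factor confounder model, planted regulatory effects, Hi-C contact
#' parameters and the GWAS sample size. The defaults describe a desk-scale
#' brain-cohort stand-in: 500 samples, 4 chromosomes of 10 Mb, 500 variants and
#' 125 genes per chromosome, LD blocks of 10 variants at a latent correlation
#' of 0.8, 5 shared hidden expression factors and unit residual noise.
#'
#' @param n_samples Number of individuals.
#' @param n_chromosomes Number of autosomes simulated.
#' @param chrom_length_bp Length of every chromosome in base pairs.
#' @param n_variants_per_chrom Variants per chromosome.
#' @param maf_range Interval in (0, 0.5] from which per-variant minor allele
#'   frequencies are drawn uniformly.
#' @param ld_block_size Number of consecutive variants sharing one LD block.
#' @param ld_within_block_r Target correlation of the latent haplotype signal
#'   within a block, in `[0, 1]`. `1` makes within-block variants exact copies.
#' @param n_genes_per_chrom Genes per chromosome.
#' @param noise_sd Standard deviation of the i.i.d. residual expression noise.
#' @param n_hidden_factors Number of shared hidden factors (confounders).
#' @param factor_sd Standard deviation of per-gene factor loadings.
#' @param effects Tibble of planted effects as built by [planted_effect()] /
#'   [plant_architecture()], or `NULL` for a pure-null cohort.
#' @param hic_resolution_bp Hi-C bin size in base pairs.
#' @param hic_baseline_mean Mean of the Poisson baseline for interchromosomal
#'   normalized contact frequencies.
#' @param hic_enrichment_factor Multiplier (>= 1) applied to the contact mean
#'   of bin pairs linked by planted interchromosomal trans effects.
#' @param gwas_n GWAS sample size used to scale summary-statistic standard
#'   errors.
#' @param gwas_causal_z Mean absolute z-score planted at GWAS causal variants.
#' @param seed Root seed; every artifact derives a named substream from it.
#'
#' @return A validated `sim_config` object (a list).
#' @seealso [simulate_cohort()], [plant_architecture()]
#' @export
sim_config <- function(n_samples = 500,
                       n_chromosomes = 4,
                       chrom_length_bp = 1e7,
                       n_variants_per_chrom = 500,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_within_block_r = 0.8,
                       n_genes_per_chrom = 125,
                       noise_sd = 1,
                       n_hidden_factors = 5,
                       factor_sd = 0.5,
                       effects = NULL,
                       hic_resolution_bp = 1e5,
                       hic_baseline_mean = 5,
                       hic_enrichment_factor = 5,
                       gwas_n = 50000,
                       gwas_causal_z = 8,
                       seed = 1) {
  assert_count(n_samples, "n_samples")
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(chrom_length_bp, "chrom_length_bp")
  assert_count(n_variants_per_chrom, "n_variants_per_chrom")
  assert_count(n_genes_per_chrom, "n_genes_per_chrom")
  assert_count(ld_block_size, "ld_block_size")
  assert_count(hic_resolution_bp, "hic_resolution_bp")
  assert_count(gwas_n, "gwas_n")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval inside (0, 0.5]")
  }
  if (ld_within_block_r < 0 || ld_within_block_r > 1) {
    abort("`ld_within_block_r` must lie in [0, 1]")
  }
  if (noise_sd < 0 || factor_sd < 0) abort("standard deviations must be >= 0")
  if (n_hidden_factors < 0) abort("`n_hidden_factors` must be >= 0")
  if (hic_baseline_mean < 0) abort("`hic_baseline_mean` must be >= 0")
  if (hic_enrichment_factor < 1) abort("`hic_enrichment_factor` must be >= 1")
  if (!is.null(effects)) effects <- validate_effects(effects)

  structure(list(
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_variants_per_chrom = as.integer(n_variants_per_chrom),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size),
    ld_within_block_r = as.numeric(ld_within_block_r),
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    noise_sd = as.numeric(noise_sd),
    n_hidden_factors = as.integer(n_hidden_factors),
    factor_sd = as.numeric(factor_sd),
    effects = effects,
    hic_resolution_bp = as.integer(hic_resolution_bp),
    hic_baseline_mean = as.numeric(hic_baseline_mean),
    hic_enrichment_factor = as.numeric(hic_enrichment_factor),
    gwas_n = as.integer(gwas_n),
    gwas_causal_z = as.numeric(gwas_causal_z),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Describe one planted regulatory effect
#'
#' An effect is one edge (or path) of the planted architecture: a `cis` effect
#' `a` of a variant on a nearby gene, a `mediated_trans` path (`a` into the cis
#' gene, `b` from the cis gene into a distal gene, optionally a residual direct
#' `c`), or a `direct_trans` effect `c` with no mediator.
#'
#' @param kind One of `"cis"`, `"mediated_trans"`, `"direct_trans"`.
#' @param variant_id Variant identifier (deterministic scheme
#'   `chr<k>_v<j>`, see [variant_ids()]).
#' @param cis_gene_id Proximal target gene (not used for `direct_trans`).
#' @param trans_gene_id Distal target gene (not used for `cis`).
#' @param a,b,c SNP-to-cis-gene, cis-gene-to-trans-gene and direct
#'   SNP-to-trans-gene effect sizes (expression units per dosage unit).
#'
#' @return One-row tibble.
#' @export
planted_effect <- function(kind, variant_id, cis_gene_id = NA_character_,
                           trans_gene_id = NA_character_, a = 0, b = 0, c = 0) {
  validate_effects(tibble(
    kind = kind, variant_id = variant_id, cis_gene_id = cis_gene_id,
    trans_gene_id = trans_gene_id, a = a, b = b, c = c
  ))
}

validate_effects <- function(effects) {
  effects <- as_tibble(effects)
  need <- c("kind", "variant_id", "cis_gene_id", "trans_gene_id", "a", "b", "c")
  miss <- setdiff(need, names(effects))
  if (length(miss)) abort(paste("effects table lacks columns:", paste(miss, collapse = ", ")))
  if (!all(effects$kind %in% c("cis", "mediated_trans", "direct_trans"))) {
    abort("effect kind must be cis, mediated_trans or direct_trans")
  }
  if (!all(is.finite(effects$a) & is.finite(effects$b) & is.finite(effects$c))) {
    abort("effect sizes must be finite")
  }
  bad <- effects$kind == "cis" & effects$a == 0
  if (any(bad)) abort("cis effects require a != 0")
  bad <- effects$kind == "mediated_trans" & (effects$a == 0 | effects$b == 0 |
                                               is.na(effects$cis_gene_id))
  if (any(bad)) abort("mediated_trans effects require a != 0, b != 0 and a cis gene")
  bad <- effects$kind != "cis" & is.na(effects$trans_gene_id)
  if (any(bad)) abort("trans effects require a trans gene")
  effects[need]
}

#' Deterministic identifier pools of a configuration
#'
#' Variant and gene identifiers are fixed by the configuration alone
#' (`chr<k>_v<j>` and `g<k>_<j>`), so planted architectures can reference them
#' before any simulation draw.
#'
#' @param config A [sim_config()].
#' @return Character vector of ids.
#' @export
variant_ids <- function(config) {
  as.vector(vapply(seq_len(config$n_chromosomes), function(k) {
    sprintf("chr%d_v%04d", k, seq_len(config$n_variants_per_chrom))
  }, character(config$n_variants_per_chrom)))
}

#' @rdname variant_ids
#' @export
gene_ids <- function(config) {
  as.vector(vapply(seq_len(config$n_chromosomes), function(k) {
    sprintf("g%d_%03d", k, seq_len(config$n_genes_per_chrom))
  }, character(config$n_genes_per_chrom)))
}

#' Plant a default regulatory architecture into a configuration
#'
#' Fills `config$effects` with `n_cis` stand-alone cis effects, `n_mediated`
#' SNP -> cis-gene -> trans-gene paths, `n_direct` direct trans effects, and
#' `n_hotspots` hotspot variants each driving `targets_per_hotspot` (>= 3)
#' distal genes through one shared cis mediator. Variants are taken from
#' distinct LD blocks (block leads, every other block) so planted signals stay
#' quasi-independent; genes are assigned without reuse. Trans target genes are
#' always placed on a different chromosome than their variant by
#' [simulate_expression()].
#'
#' @param config A [sim_config()].
#' @param n_cis,n_mediated,n_direct Numbers of planted effects of each kind.
#' @param n_hotspots Number of hotspot variants.
#' @param targets_per_hotspot Trans targets per hotspot (>= 3).
#' @param a,b,c Effect sizes used for all planted paths.
#' @param n_gwas_causal How many planted trans-effect variants also carry a
#'   GWAS signal (taken from the mediated then direct lists in order).
#'
#' @return The configuration with `effects` (and the GWAS causal set) filled.
#' @export
plant_architecture <- function(config, n_cis = 20, n_mediated = 20,
                               n_direct = 10, n_hotspots = 5,
                               targets_per_hotspot = 4,
                               a = 1, b = 1, c = 1, n_gwas_causal = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (n_hotspots > 0 && targets_per_hotspot < 3) {
    abort("hotspots require >= 3 targets each")
  }
  vids <- variant_ids(config)
  gids <- gene_ids(config)
  # block leads, every other block, round-robin across chromosomes
  leads <- which((seq_along(vids) - 1L) %% (2L * config$ld_block_size) == 0L)
  n_need_v <- n_cis + n_mediated + n_direct + n_hotspots
  if (length(leads) < n_need_v) abort("not enough LD blocks for the requested architecture")
  vs <- vids[leads[seq_len(n_need_v)]]
  n_need_g <- n_cis + 2L * n_mediated + n_direct + n_hotspots * (1L + targets_per_hotspot)
  if (length(gids) < n_need_g) abort("not enough genes for the requested architecture")
  gpool <- gids
  take_genes <- function(k) {
    out <- gpool[seq_len(k)]
    gpool <<- gpool[-seq_len(k)]
    out
  }

  rows <- list()
  vi <- 0L
  for (i in seq_len(n_cis)) {
    vi <- vi + 1L
    rows[[length(rows) + 1L]] <- tibble(
      kind = "cis", variant_id = vs[vi], cis_gene_id = take_genes(1L),
      trans_gene_id = NA_character_, a = a, b = 0, c = 0
    )
  }
  for (i in seq_len(n_mediated)) {
    vi <- vi + 1L
    g2 <- take_genes(2L)
    rows[[length(rows) + 1L]] <- tibble(
      kind = "mediated_trans", variant_id = vs[vi], cis_gene_id = g2[1],
      trans_gene_id = g2[2], a = a, b = b, c = 0
    )
  }
  for (i in seq_len(n_direct)) {
    vi <- vi + 1L
    rows[[length(rows) + 1L]] <- tibble(
      kind = "direct_trans", variant_id = vs[vi], cis_gene_id = NA_character_,
      trans_gene_id = take_genes(1L), a = 0, b = 0, c = c
    )
  }
  for (i in seq_len(n_hotspots)) {
    vi <- vi + 1L
    med <- take_genes(1L)
    tg <- take_genes(targets_per_hotspot)
    rows[[length(rows) + 1L]] <- tibble(
      kind = "mediated_trans", variant_id = vs[vi], cis_gene_id = med,
      trans_gene_id = tg, a = a, b = b, c = 0
    )
  }
  effects <- validate_effects(bind_rows(rows))
  config$effects <- effects
  trans_vars <- unique(effects$variant_id[effects$kind != "cis"])
  config$gwas_causal_variants <- head(trans_vars, n_gwas_causal)
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples, %d chromosomes x %s bp\n", x$n_samples,
              x$n_chromosomes, format(x$chrom_length_bp, big.mark = ",")))
  cat(sprintf("  %d variants/chrom (LD blocks of %d, latent r = %.2f), %d genes/chrom\n",
              x$n_variants_per_chrom, x$ld_block_size, x$ld_within_block_r,
              x$n_genes_per_chrom))
  cat(sprintf("  %d hidden factors (loading sd %.2f), noise sd %.2f\n",
              x$n_hidden_factors, x$factor_sd, x$noise_sd))
  cat(sprintf("  planted effects: %d; seed %d\n",
              if (is.null(x$effects)) 0L else nrow(x$effects), x$seed))
  invisible(x)
}
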