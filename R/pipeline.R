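#' Run the standard trans-eQTL discovery pipeline on a cohort
#'
#' Convenience composition of the discovery stages: expression normalization
#' (detection filter, quantile normalization, inverse normal transform),
#' covariate construction (expression hidden factors + genotype PCs),
#' nominal trans and cis scans, pooled Benjamini--Hochberg selection of
#' candidate trans-eQTLs, and greedy LD pruning of the candidates into
#' independent signals.
#'
#' By default BH runs over the full trans record list and the significant
#' candidates are then LD-pruned. The reverse order (`order =
#' "prune_then_fdr"`, BH over the pruned record list) is available, but note
#' that greedy pruning keeps each LD clump's smallest p, so computing BH on
#' that selected subset is anti-conservative under the global null.
#'
#' @param cohort A `trans_cohort` from [simulate_cohort()], or any list with
#'   `expression` and `genotypes` entries.
#' @param n_factors Hidden expression factors used as covariates.
#' @param n_pcs Genotype principal components used as covariates.
#' @param alpha Pooled FDR threshold for the trans list.
#' @param r2_threshold LD-pruning threshold.
#' @param blacklist Optional cross-mappability blacklist for
#'   [cross_map_filter()].
#' @param order `"fdr_then_prune"` (default) or `"prune_then_fdr"`.
#' @return List with `normalized`, `residual` (normalized expression with the
#'   covariates regressed out -- the matrix co-expression statistics should
#'   use, since shared hidden factors would otherwise inflate between-gene
#'   correlations), `covariates`, `trans`, `cis`, `candidates` (the
#'   significant list before pruning) and `hits` (independent signals after
#'   pruning).
#' @examples
#' cohort <- simulate_cohort(plant_architecture(
#'   sim_config(n_samples = 150, n_variants_per_chrom = 100,
#'              n_genes_per_chrom = 30, seed = 5),
#'   n_cis = 2, n_mediated = 2, n_direct = 1, n_hotspots = 1
#' ))
#' res <- qtl_pipeline(cohort, n_factors = 2, n_pcs = 2)
#' nrow(res$hits)
#' @export
qtl_pipeline <- function(cohort, n_factors = 5, n_pcs = 3, alpha = 0.25,
                         r2_threshold = 0.6, blacklist = NULL,
                         order = c("fdr_then_prune", "prune_then_fdr")) {
  order <- match.arg(order)
  nx <- normalize_expression(cohort$expression)
  cv <- if (n_factors > 0 || n_pcs > 0) {
    build_covariates(nx, cohort$genotypes, n_factors = n_factors,
                     n_pcs = n_pcs)
  } else NULL
  trans <- nominal_scan(nx, cohort$genotypes, cv, mode = "trans")
  cis <- nominal_scan(nx, cohort$genotypes, cv, mode = "cis")
  if (!is.null(blacklist)) trans <- cross_map_filter(trans, blacklist)
  if (order == "fdr_then_prune") {
    candidates <- pooled_fdr(trans, alpha)
    hits <- ld_prune(candidates, cohort$genotypes, r2_threshold = r2_threshold)
  } else {
    candidates <- ld_prune(trans, cohort$genotypes, r2_threshold = r2_threshold)
    hits <- pooled_fdr(candidates, alpha)
  }
  list(normalized = nx,
       residual = expression_matrix(residualize(nx$values, cv), nx$genes),
       covariates = cv, trans = trans, cis = cis,
       candidates = candidates, hits = hits)
}

#' Build the Hi-C pair table for a trans-eQTL list
#'
#' Joins variant positions and gene TSS coordinates onto a (variant, gene)
#' list so it can feed [interchromosomal_enrichment()].
#'
#' @param qtl_list Tibble with `variant_id`, `gene_id`.
#' @param genotypes A `genotype_matrix`.
#' @param expr An `expression_matrix`.
#' @return Tibble with `chrom_snp`, `pos_snp`, `chrom_gene`, `tss_gene`.
#' @export
qtl_pair_positions <- function(qtl_list, genotypes, expr) {
  qtl_list |>
    left_join(genotypes$variants[, c("variant_id", "chrom", "pos")],
              by = "variant_id") |>
    left_join(expr$genes[, c("gene_id", "chrom", "tss")],
              by = "gene_id", suffix = c("_v", "_g")) |>
    dplyr::transmute(chrom_snp = .data$chrom_v, pos_snp = .data$pos,
                     chrom_gene = .data$chrom_g, tss_gene = .data$tss)
}
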