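#' Simulate a complete cohort with planted regulatory architecture
#'
#' Runs the four generators off one root seed (named substreams per artifact):
#' genotypes, expression plus ground truth, the Hi-C contact matrix and the
#' GWAS summary statistics.
#'
#' @param config A [sim_config()]; plant effects first with
#'   [plant_architecture()] (or leave `effects = NULL` for a null cohort).
#' @return A `trans_cohort` list: `genotypes`, `expression`, `truth`,
#'   `contacts`, `gwas`, `config`.
#' @examples
#' cfg <- sim_config(n_samples = 100, n_variants_per_chrom = 50,
#'                   n_genes_per_chrom = 20, seed = 7)
#' cohort <- simulate_cohort(plant_architecture(cfg, n_cis = 2, n_mediated = 2,
#'                                              n_direct = 1, n_hotspots = 1))
#' cohort
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- simulate_genotypes(config)
  ex <- simulate_expression(genotypes, config)
  contacts <- simulate_contact_matrix(ex$truth, config)
  gwas <- simulate_gwas_summary(genotypes, ex$truth, config)
  structure(list(
    genotypes = genotypes, expression = ex$expression, truth = ex$truth,
    contacts = contacts, gwas = gwas, config = config
  ), class = "trans_cohort")
}

#' @export
print.trans_cohort <- function(x, ...) {
  cat("<trans_cohort>\n")
  print(x$genotypes)
  print(x$expression)
  print(x$truth)
  cat(sprintf("  contacts: %d interchromosomal bin pairs at %s bp\n",
              nrow(x$contacts),
              format(attr(x$contacts, "resolution_bp"), big.mark = ",")))
  cat(sprintf("  gwas: %d variants, n = %d\n", nrow(x$gwas), x$gwas$n[1]))
  invisible(x)
}
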