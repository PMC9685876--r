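#' Simulate expression with planted cis, mediated-trans and direct-trans effects
#'
#' Builds a genes x samples expression matrix from three additive parts:
#' shared hidden factors (loadings `N(0, factor_sd^2)` on `n_hidden_factors`
#' standard-normal factors per sample), i.i.d. residual noise
#' `N(0, noise_sd^2)`, and the planted effects. A cis target gene receives
#' `a * g` for its variant's dosage `g`; a trans target receives
#' `b * y_cis + c * g` where `y_cis` is the realized expression of the mediator
#' (so mediated targets inherit the mediator's noise and factor structure, as a
#' real regulatory cascade would).
#'
#' Gene placement: genes get random TSS positions; the cis gene of a planted
#' effect is moved next to its variant (TSS = variant position + 10 kb, same
#' chromosome) and a trans target gene is moved to a different chromosome than
#' its variant, so planted labels always match the scan's cis/trans windows.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param config The same [sim_config()] used for the genotypes.
#' @return List with `expression` (an `expression_matrix`) and `truth`
#'   (a `regulatory_truth`).
#' @export
simulate_expression <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  effects <- config$effects %||%
    tibble(kind = character(), variant_id = character(),
           cis_gene_id = character(), trans_gene_id = character(),
           a = numeric(), b = numeric(), c = numeric())
  ids_needed <- setdiff(
    unique(c(effects$variant_id)),
    genotypes$variants$variant_id
  )
  if (length(ids_needed)) {
    abort(paste("planted variants not simulated:", paste(ids_needed, collapse = ", ")))
  }

  withr::with_seed(substream_seed(config$seed, "expression"), {
    n <- config$n_samples
    G <- config$n_genes_per_chrom
    genes <- bind_rows(lapply(seq_len(config$n_chromosomes), function(chrom) {
      tibble(
        gene_id = sprintf("g%d_%03d", chrom, seq_len(G)),
        chrom = chrom,
        tss = sort(sample.int(config$chrom_length_bp - 1L, G)),
        strand = sample(c("+", "-"), G, replace = TRUE)
      )
    }))
    gene_pool <- setdiff(genes$gene_id,
                         c(effects$cis_gene_id, effects$trans_gene_id))
    bad <- setdiff(stats::na.omit(c(effects$cis_gene_id, effects$trans_gene_id)),
                   genes$gene_id)
    if (length(bad)) {
      abort(paste("planted genes not simulated:", paste(bad, collapse = ", ")))
    }

    # relocate planted genes so cis/trans labels hold by construction
    vtab <- genotypes$variants
    for (i in seq_len(nrow(effects))) {
      v <- vtab[vtab$variant_id == effects$variant_id[i], ]
      if (!is.na(effects$cis_gene_id[i])) {
        j <- match(effects$cis_gene_id[i], genes$gene_id)
        genes$chrom[j] <- v$chrom
        genes$tss[j] <- as.integer(min(v$pos + 10000L, config$chrom_length_bp - 1L))
      }
      if (!is.na(effects$trans_gene_id[i])) {
        for (tg in effects$trans_gene_id[i]) {
          j <- match(tg, genes$gene_id)
          if (genes$chrom[j] == v$chrom) {
            genes$chrom[j] <- (v$chrom %% config$n_chromosomes) + 1L
          }
        }
      }
    }

    n_genes <- nrow(genes)
    values <- matrix(rnorm(n_genes * n, sd = config$noise_sd), nrow = n_genes)
    factors <- NULL
    if (config$n_hidden_factors > 0) {
      factors <- matrix(rnorm(n * config$n_hidden_factors), nrow = n)
      loadings <- matrix(rnorm(n_genes * config$n_hidden_factors,
                               sd = config$factor_sd), nrow = n_genes)
      values <- values + loadings %*% t(factors)
    }
    rownames(values) <- genes$gene_id
    colnames(values) <- rownames(genotypes$dosage)

    # cis effects first so mediated targets see the realized mediator;
    # hotspot rows share one (variant, mediator) pair -> apply it once
    cis_adds <- effects |>
      filter(.data$a != 0) |>
      distinct(.data$variant_id, .data$cis_gene_id, .data$a)
    for (i in seq_len(nrow(cis_adds))) {
      g <- genotypes$dosage[, cis_adds$variant_id[i]]
      j <- match(cis_adds$cis_gene_id[i], genes$gene_id)
      values[j, ] <- values[j, ] + cis_adds$a[i] * g
    }
    for (i in which(effects$kind != "cis")) {
      g <- genotypes$dosage[, effects$variant_id[i]]
      j <- match(effects$trans_gene_id[i], genes$gene_id)
      med <- if (!is.na(effects$cis_gene_id[i])) {
        values[match(effects$cis_gene_id[i], genes$gene_id), ]
      } else 0
      values[j, ] <- values[j, ] + effects$b[i] * med + effects$c[i] * g
    }

    truth <- regulatory_truth(effects, genotypes, genes, config)
    list(expression = expression_matrix(values, genes), truth = truth)
  })
}

regulatory_truth <- function(effects, genotypes, genes, config) {
  trans <- effects[effects$kind != "cis", ]
  hotspot_variants <- trans |>
    distinct(.data$variant_id, .data$trans_gene_id) |>
    dplyr::count(.data$variant_id) |>
    filter(.data$n >= 3) |>
    pull(.data$variant_id)

  res <- config$hic_resolution_bp
  vtab <- genotypes$variants
  pairs <- trans |>
    left_join(vtab[, c("variant_id", "chrom", "pos")], by = "variant_id") |>
    left_join(genes[, c("gene_id", "chrom", "tss")],
              by = c(trans_gene_id = "gene_id"), suffix = c("_v", "_g")) |>
    filter(.data$chrom_v != .data$chrom_g) |>
    mutate(bin_v = .data$pos %/% res, bin_g = .data$tss %/% res)
  enriched <- tibble(
    chrom_a = pmin(pairs$chrom_v, pairs$chrom_g),
    bin_a = ifelse(pairs$chrom_v <= pairs$chrom_g, pairs$bin_v, pairs$bin_g),
    chrom_b = pmax(pairs$chrom_v, pairs$chrom_g),
    bin_b = ifelse(pairs$chrom_v <= pairs$chrom_g, pairs$bin_g, pairs$bin_v)
  ) |> distinct()

  gwas_causal <- config$gwas_causal_variants %||% unique(trans$variant_id)
  structure(list(
    effects = effects,
    hotspot_variants = hotspot_variants,
    enriched_contact_pairs = enriched,
    gwas_causal_variants = gwas_causal
  ), class = "regulatory_truth")
}

#' Planted trans (variant, gene) pairs of a truth object
#'
#' @param truth A `regulatory_truth`.
#' @return Tibble of `variant_id`, `gene_id`, `kind`.
#' @export
true_trans_pairs <- function(truth) {
  stopifnot(inherits(truth, "regulatory_truth"))
  truth$effects |>
    filter(.data$kind != "cis") |>
    distinct(.data$variant_id, gene_id = .data$trans_gene_id, .data$kind)
}

#' @export
print.regulatory_truth <- function(x, ...) {
  cat(sprintf("<regulatory_truth> %d planted effects (%d hotspot variants, %d enriched contact pairs, %d GWAS causal variants)\n",
              nrow(x$effects), length(x$hotspot_variants),
              nrow(x$enriched_contact_pairs), length(x$gwas_causal_variants)))
  invisible(x)
}

#' Construct an expression container
#'
#' @param values Genes x samples numeric matrix with dimnames.
#' @param genes Tibble with `gene_id`, `chrom`, `tss`, `strand` matching rows.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, genes) {
  genes <- as_tibble(genes)
  if (anyDuplicated(genes$gene_id)) abort("gene ids must be unique")
  if (is.null(rownames(values))) rownames(values) <- genes$gene_id
  if (!identical(rownames(values), genes$gene_id)) {
    abort("expression rows and gene table are not aligned")
  }
  structure(list(values = values, genes = genes), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
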