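#' Define genome-wide-significant GWAS loci by LD clumping
#'
#' Iterative greedy clumping: the smallest-p unassigned variant below
#' `p_threshold` becomes a locus index; every variant with squared dosage
#' correlation above `r2` with the index (same chromosome, index included)
#' joins the locus and is removed from further consideration; repeat until no
#' significant variant remains. Every significant variant is assigned to
#' exactly one locus.
#'
#' @param gwas A `gwas_summary` tibble (`variant_id`, `chrom`, `pos`, `p`).
#' @param genotypes A `genotype_matrix` serving as the LD reference.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2 LD threshold for locus membership (default 0.6).
#' @return Tibble per locus: `locus_id`, `index_variant`, `chrom`, `start`,
#'   `end`, `n_members`, `members` (list column).
#' @export
define_gws_loci <- function(gwas, genotypes, p_threshold = 5e-8, r2 = 0.6) {
  sig <- gwas |> filter(.data$p < p_threshold)
  if (nrow(sig) == 0) {
    return(tibble(locus_id = character(), index_variant = character(),
                  chrom = integer(), start = integer(), end = integer(),
                  n_members = integer(), members = list()))
  }
  in_ref <- gwas$variant_id %in% colnames(genotypes$dosage)
  if (!all(sig$variant_id %in% colnames(genotypes$dosage))) {
    abort("LD reference does not cover all significant GWAS variants")
  }
  assigned <- character()
  loci <- list()
  repeat {
    open <- sig |> filter(!.data$variant_id %in% assigned)
    if (nrow(open) == 0) break
    index <- open$variant_id[which.min(open$p)]
    ichrom <- open$chrom[which.min(open$p)]
    on_c <- gwas |>
      filter(.data$chrom == ichrom, in_ref[match(.data$variant_id, gwas$variant_id)],
             !.data$variant_id %in% assigned)
    r2v <- as.vector(cor(genotypes$dosage[, on_c$variant_id, drop = FALSE],
                         genotypes$dosage[, index]))^2
    members <- on_c$variant_id[r2v > r2 | on_c$variant_id == index]
    assigned <- c(assigned, members)
    mpos <- gwas$pos[match(members, gwas$variant_id)]
    loci[[length(loci) + 1L]] <- tibble(
      locus_id = sprintf("locus_%03d", length(loci) + 1L),
      index_variant = index, chrom = ichrom,
      start = min(mpos), end = max(mpos),
      n_members = length(members), members = list(members)
    )
  }
  bind_rows(loci)
}

#' Colocalize QTL records with GWAS loci to call risk genes
#'
#' Restricts the QTL records to nominal `p < qtl_p_max`, intersects them with
#' each locus' member variants, and for every (gene, locus) with at least two
#' variants shared between the QTL and GWAS traces runs [coloc_posteriors()].
#' Calls with `pp4 > pp4_threshold` are emitted as risk-gene calls.
#'
#' @param qtl_records Association tibble (`variant_id`, `gene_id`, `beta`,
#'   `se`, `p`).
#' @param gwas A `gwas_summary` tibble.
#' @param loci Locus tibble from [define_gws_loci()].
#' @param qtl_p_max Nominal QTL p ceiling before colocalization (1e-5).
#' @param pp4_threshold Shared-causal-variant posterior threshold (0.6).
#' @param mode Label recorded on each call (`"trans"` or `"cis"`).
#' @param W_qtl,W_gwas Prior effect variances for the two traces.
#' @param p1,p2,p12 Colocalization priors.
#' @return Tibble of calls: `gene_id`, `locus_id`, `mode`, `n_shared`,
#'   `pp4` (plus `pp0`..`pp3`); attribute `skipped` counts (gene, locus)
#'   combinations with fewer than two shared variants.
#' @export
gwas_coloc <- function(qtl_records, gwas, loci, qtl_p_max = 1e-5,
                       pp4_threshold = 0.6, mode = "trans",
                       W_qtl = 0.15^2, W_gwas = 0.15^2,
                       p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  qtl <- qtl_records |> filter(.data$p < qtl_p_max)
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(loci))) {
    members <- loci$members[[i]]
    in_locus <- qtl |> filter(.data$variant_id %in% members)
    for (g in unique(in_locus$gene_id)) {
      g_all <- qtl_records |>
        filter(.data$gene_id == g, .data$variant_id %in% members)
      shared <- intersect(g_all$variant_id, gwas$variant_id)
      if (length(shared) < 2) {
        skipped <- skipped + 1L
        warn(sprintf("(%s, %s): fewer than 2 shared variants, skipped",
                     g, loci$locus_id[i]))
        next
      }
      qt <- g_all[match(shared, g_all$variant_id), ]
      gw <- gwas[match(shared, gwas$variant_id), ]
      res <- coloc_posteriors(
        wakefield_abf(qt$beta, qt$se, W_qtl),
        wakefield_abf(gw$beta, gw$se, W_gwas),
        p1 = p1, p2 = p2, p12 = p12
      )
      out[[length(out) + 1L]] <- tibble(
        gene_id = g, locus_id = loci$locus_id[i], mode = mode,
        n_shared = length(shared),
        pp0 = res$pp[["pp0"]], pp1 = res$pp[["pp1"]], pp2 = res$pp[["pp2"]],
        pp3 = res$pp[["pp3"]], pp4 = res$pp[["pp4"]]
      )
    }
  }
  calls <- if (length(out)) bind_rows(out) |> filter(.data$pp4 > pp4_threshold)
           else tibble(gene_id = character(), locus_id = character(),
                       mode = character(), n_shared = integer(),
                       pp0 = numeric(), pp1 = numeric(), pp2 = numeric(),
                       pp3 = numeric(), pp4 = numeric())
  structure(calls, skipped = skipped)
}

#' Annotate loci by the QTL modes that colocalize with them
#'
#' @param loci Locus tibble from [define_gws_loci()].
#' @param trans_calls,cis_calls Call tibbles from [gwas_coloc()] run in trans
#'   and cis mode (either may be empty).
#' @return Tibble per locus with `annotation` in
#'   `{"both", "trans_only", "cis_only", "unannotated"}`.
#' @export
locus_annotation <- function(loci, trans_calls, cis_calls = NULL) {
  t_loci <- unique(trans_calls$locus_id)
  c_loci <- if (is.null(cis_calls)) character() else unique(cis_calls$locus_id)
  loci |>
    mutate(annotation = dplyr::case_when(
      .data$locus_id %in% t_loci & .data$locus_id %in% c_loci ~ "both",
      .data$locus_id %in% t_loci ~ "trans_only",
      .data$locus_id %in% c_loci ~ "cis_only",
      TRUE ~ "unannotated"
    )) |>
    select("locus_id", "index_variant", "annotation")
}

#' Fisher enrichment between an eGene set and an annotation gene set
#'
#' Builds the 2x2 membership table over a background gene list and reports
#' the two-sided Fisher exact p together with the sample odds ratio
#' `ad / bc`; when any cell is zero the Haldane--Anscombe 0.5 correction is
#' applied to the odds ratio and its Woolf (log-normal) 95% confidence
#' interval.
#'
#' @param egene_set,annotation_set Character vectors of gene ids (subsets of
#'   `background`).
#' @param background Character vector: the background gene universe.
#' @return One-row tibble: `odds_ratio`, `ci_low`, `ci_high`, `p`, `a`, `b`,
#'   `c`, `d`.
#' @export
gene_set_fisher <- function(egene_set, annotation_set, background) {
  if (length(background) == 0) abort("background gene list is empty")
  egene_set <- intersect(unique(egene_set), background)
  annotation_set <- intersect(unique(annotation_set), background)
  in_e <- background %in% egene_set
  in_a <- background %in% annotation_set
  a <- sum(in_e & in_a)
  b <- sum(in_e & !in_a)
  cc <- sum(!in_e & in_a)
  d <- sum(!in_e & !in_a)
  p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se_log <- sqrt(sum(1 / cells))
  tibble(
    odds_ratio = or,
    ci_low = exp(log(or) - 1.96 * se_log),
    ci_high = exp(log(or) + 1.96 * se_log),
    p = p, a = a, b = b, c = cc, d = d
  )
}
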