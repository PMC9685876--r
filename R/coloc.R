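#' Wakefield log approximate Bayes factor
#'
#' Single-variant Bayes factor of association against the null from an effect
#' estimate and its standard error, under a `N(0, W)` effect prior:
#' with shrinkage `W / (W + se^2)` (call it rho) and `z = beta / se`,
#' `log ABF = 0.5 * log(1 - rho) + 0.5 * z^2 * rho`.
#'
#' The default prior variance `W = 0.15^2` is the standard choice for
#' quantitative traits measured on a unit-variance scale (which the inverse
#' normal transform guarantees for expression).
#'
#' @param beta Effect estimates.
#' @param se Standard errors (> 0).
#' @param W Prior effect variance (>= 0).
#' @return Vector of log approximate Bayes factors.
#' @export
wakefield_abf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) abort("standard errors must be > 0")
  if (W < 0) abort("prior variance W must be >= 0")
  r <- W / (W + se^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Colocalization posteriors from two per-variant log-ABF traces
#'
#' Enumerates the single-causal-variant configurations of the five-hypothesis
#' model (H0 no association; H1/H2 one trait only; H3 two distinct causal
#' variants; H4 one shared causal variant), weighting configurations by the
#' per-variant priors `p1`, `p2`, `p12`, entirely in log space.
#'
#' @param labf1,labf2 Log approximate Bayes factors of the two traits over an
#'   identical variant ordering.
#' @param p1,p2,p12 Prior probabilities that a variant is causal for trait 1
#'   only, trait 2 only, or both (defaults are the conventional
#'   `1e-4, 1e-4, 1e-5`).
#' @return A `coloc_result`: list with `pp` (named posteriors `pp0`..`pp4`
#'   summing to 1), `n_variants` and `priors`.
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (length(labf1) != length(labf2)) abort("trait traces differ in length")
  if (length(labf1) < 1) abort("at least one variant is required")
  s1 <- logsumexp(labf1)
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  structure(list(
    pp = setNames(as.numeric(pp), paste0("pp", 0:4)),
    n_variants = length(labf1),
    priors = c(p1 = p1, p2 = p2, p12 = p12)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d variants | %s\n", x$n_variants,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  invisible(x)
}

#' Colocalize cis and trans association traces around independent trans-eSNPs
#'
#' For each independent (LD-pruned) trans-eQTL record, collects the variants
#' in LD (`r^2 > r2_threshold`) with its eSNP, finds every cis gene with
#' association records on those variants, and runs [coloc_posteriors()] over
#' the variants shared between the trans gene's and the cis gene's traces.
#' Pairs with fewer than two shared variants are skipped with a warning.
#'
#' @param trans_hits Independent trans records (tibble: `variant_id`,
#'   `gene_id`), e.g. a pooled-FDR list after [ld_prune()].
#' @param cis_records Nominal cis association tibble (`variant_id`, `gene_id`,
#'   `beta`, `se`).
#' @param trans_records Nominal trans association tibble covering the trans
#'   genes' traces over the candidate variants.
#' @param genotypes A `genotype_matrix` for LD computation.
#' @param r2_threshold LD partner threshold (default 0.6).
#' @param pp4_threshold Emit pairs with shared-variant posterior above this
#'   (default 0.5); set `keep_all = TRUE` to return every tested pair.
#' @param W,p1,p2,p12 Prior parameters passed to the ABF machinery.
#' @param keep_all Return all tested pairs with a `selected` flag.
#' @return Tibble per tested (trans eSNP, trans gene, cis gene): `n_shared`,
#'   `pp0`..`pp4`, `selected`.
#' @export
colocalize_cis_trans <- function(trans_hits, cis_records, trans_records,
                                 genotypes, r2_threshold = 0.6,
                                 pp4_threshold = 0.5, W = 0.15^2,
                                 p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                                 keep_all = FALSE) {
  hits <- distinct(trans_hits, .data$variant_id, .data$gene_id)
  if (nrow(hits) == 0) return(empty_coloc_pairs())
  vtab <- genotypes$variants
  # index record tables once; the loop works on plain vectors for speed
  trans_by_gene <- split(seq_len(nrow(trans_records)), trans_records$gene_id)
  cis_by_var <- split(seq_len(nrow(cis_records)), cis_records$variant_id)
  t_var <- trans_records$variant_id
  t_beta <- trans_records$beta
  t_se <- trans_records$se
  c_var <- cis_records$variant_id
  c_gene <- cis_records$gene_id
  c_beta <- cis_records$beta
  c_se <- cis_records$se
  acc <- list(variant_id = character(), trans_gene = character(),
              cis_gene = character(), n_shared = integer())
  pp_rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(hits))) {
    esnp <- hits$variant_id[i]
    tgene <- hits$gene_id[i]
    chrom <- vtab$chrom[vtab$variant_id == esnp]
    on_c <- vtab$variant_id[vtab$chrom == chrom]
    r2 <- as.vector(cor(genotypes$dosage[, on_c, drop = FALSE],
                        genotypes$dosage[, esnp]))^2
    partners <- on_c[r2 > r2_threshold]
    rows_t <- trans_by_gene[[tgene]]
    rows_t <- rows_t[t_var[rows_t] %in% partners]
    cis_rows <- unlist(cis_by_var[intersect(partners, names(cis_by_var))],
                       use.names = FALSE)
    for (cg in unique(c_gene[cis_rows])) {
      rows_c <- cis_rows[c_gene[cis_rows] == cg]
      shared <- intersect(c_var[rows_c], t_var[rows_t])
      if (length(shared) < 2) {
        skipped <- skipped + 1L
        next
      }
      ci <- rows_c[match(shared, c_var[rows_c])]
      ti <- rows_t[match(shared, t_var[rows_t])]
      res <- coloc_posteriors(
        wakefield_abf(c_beta[ci], c_se[ci], W),
        wakefield_abf(t_beta[ti], t_se[ti], W),
        p1 = p1, p2 = p2, p12 = p12
      )
      acc$variant_id <- c(acc$variant_id, esnp)
      acc$trans_gene <- c(acc$trans_gene, tgene)
      acc$cis_gene <- c(acc$cis_gene, cg)
      acc$n_shared <- c(acc$n_shared, length(shared))
      pp_rows[[length(pp_rows) + 1L]] <- res$pp
    }
  }
  if (skipped > 0) {
    warn(sprintf("%d candidate pair(s) skipped with fewer than 2 shared variants", skipped))
  }
  if (!length(pp_rows)) return(empty_coloc_pairs())
  pp <- do.call(rbind, pp_rows)
  pairs <- tibble(
    variant_id = acc$variant_id, trans_gene = acc$trans_gene,
    cis_gene = acc$cis_gene, n_shared = acc$n_shared,
    pp0 = pp[, 1], pp1 = pp[, 2], pp2 = pp[, 3], pp3 = pp[, 4], pp4 = pp[, 5]
  ) |>
    distinct(.data$trans_gene, .data$cis_gene, .keep_all = TRUE) |>
    mutate(selected = .data$pp4 > pp4_threshold)
  if (keep_all) pairs else filter(pairs, .data$selected)
}

empty_coloc_pairs <- function() {
  tibble(variant_id = character(), trans_gene = character(),
         cis_gene = character(), n_shared = integer(),
         pp0 = numeric(), pp1 = numeric(), pp2 = numeric(),
         pp3 = numeric(), pp4 = numeric(), selected = logical())
}
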