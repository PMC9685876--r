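#' Map genomic positions to fixed-resolution Hi-C bins
#'
#' 0-based half-open binning: `bin = floor(pos / resolution_bp)`. Genes are
#' anchored at their TSS, variants at their position.
#'
#' @param positions Tibble with `chrom` and `pos` columns.
#' @param resolution_bp Bin size (> 0).
#' @return The tibble with a `bin` column added.
#' @export
map_to_bins <- function(positions, resolution_bp = 1e5) {
  if (resolution_bp <= 0) abort("resolution must be > 0")
  if (any(positions$pos < 0)) abort("positions must be >= 0")
  mutate(positions, bin = as.integer(.data$pos %/% resolution_bp))
}

#' Interchromosomal Hi-C contact enrichment of trans-eQTL pairs
#'
#' Tests whether interchromosomal trans-eSNP / trans-eGene pairs sit in Hi-C
#' bins with elevated normalized contact frequency. Observed values are the
#' non-zero frequencies at (eSNP bin, gene-TSS bin); the null draws
#' `n_random` bin pairs uniformly with the same chromosome-pair composition
#' as the observed set (the observed chromosome pairs recycled in order, so
#' the null's chromosome-pair multiset is the observed multiset repeated) and
#' keeps their non-zero frequencies. The comparison is a one-sided Wilcoxon
#' rank-sum test (observed greater), which is invariant to global rescaling
#' of the contact matrix.
#'
#' @param qtl_pairs Tibble with `chrom_snp`, `pos_snp`, `chrom_gene`,
#'   `tss_gene` for each trans pair; same-chromosome rows are excluded with a
#'   logged count.
#' @param contacts A `contact_matrix`.
#' @param n_random Number of random bin pairs.
#' @param seed Seed for the random draws.
#' @return A `hic_enrichment` list: `p`, `median_observed`, `median_random`,
#'   `n_observed` (non-zero retained), `n_dropped_zero`,
#'   `n_dropped_same_chrom`, `observations` tibble (`group`, `freq`).
#' @export
interchromosomal_enrichment <- function(qtl_pairs, contacts, n_random = 1000,
                                        seed = 1) {
  res <- attr(contacts, "resolution_bp")
  n_bins <- attr(contacts, "n_bins")
  same <- qtl_pairs$chrom_snp == qtl_pairs$chrom_gene
  if (any(same)) {
    inform(sprintf("excluding %d same-chromosome pair(s)", sum(same)))
    qtl_pairs <- qtl_pairs[!same, , drop = FALSE]
  }
  if (nrow(qtl_pairs) == 0) abort("no interchromosomal pairs to test")
  bin_snp <- as.integer(qtl_pairs$pos_snp %/% res)
  bin_gene <- as.integer(qtl_pairs$tss_gene %/% res)
  obs_freq <- contact_frequency(contacts, qtl_pairs$chrom_snp, bin_snp,
                                qtl_pairs$chrom_gene, bin_gene)
  n_zero <- sum(obs_freq == 0)
  obs <- obs_freq[obs_freq > 0]
  if (length(obs) == 0) {
    return(structure(list(
      p = NA_real_, median_observed = NA_real_, median_random = NA_real_,
      n_observed = 0L, n_dropped_zero = n_zero,
      n_dropped_same_chrom = sum(same),
      observations = tibble(group = character(), freq = numeric()),
      message = "no testable pairs: all observed frequencies are zero"
    ), class = "hic_enrichment"))
  }

  k <- nrow(qtl_pairs)
  idx <- ((seq_len(n_random) - 1L) %% k) + 1L
  ca <- qtl_pairs$chrom_snp[idx]
  cb <- qtl_pairs$chrom_gene[idx]
  rnd_freq <- with_seed_if(seed, {
    ba <- vapply(ca, function(ch) sample.int(n_bins[[as.character(ch)]], 1L) - 1L,
                 integer(1))
    bb <- vapply(cb, function(ch) sample.int(n_bins[[as.character(ch)]], 1L) - 1L,
                 integer(1))
    contact_frequency(contacts, ca, ba, cb, bb)
  })
  rnd <- rnd_freq[rnd_freq > 0]
  p <- suppressWarnings(
    wilcox.test(obs, rnd, alternative = "greater")$p.value
  )
  structure(list(
    p = p,
    median_observed = median(obs),
    median_random = median(rnd),
    n_observed = length(obs),
    n_random_retained = length(rnd),
    n_dropped_zero = n_zero,
    n_dropped_same_chrom = sum(same),
    null_chrom_pairs = tibble(chrom_a = pmin(ca, cb), chrom_b = pmax(ca, cb)),
    observations = bind_rows(tibble(group = "qtl", freq = obs),
                             tibble(group = "random", freq = rnd))
  ), class = "hic_enrichment")
}

#' @export
print.hic_enrichment <- function(x, ...) {
  cat(sprintf(
    "<hic_enrichment> %d non-zero QTL pairs vs %d random (dropped: %d zero, %d same-chrom)\n  median %.3g vs %.3g, one-sided rank-sum p = %.3g\n",
    x$n_observed, x$n_random_retained %||% 0L, x$n_dropped_zero,
    x$n_dropped_same_chrom, x$median_observed, x$median_random, x$p))
  invisible(x)
}
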