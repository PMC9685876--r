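#' Enrichment of QTL variants in genomic elements
#'
#' For each named element interval set, builds the 2x2 table of (inside /
#' outside element) x (QTL set / background minus QTL) and reports the sample
#' odds ratio `ad / bc`, the two-sided Fisher exact p, and the proportion of
#' QTL variants falling inside the element.
#'
#' @param variants Tibble of all background variants: `variant_id`, `chrom`,
#'   `pos` (the set used for QTL calculations).
#' @param qtl_ids Character vector of QTL variant ids (should be a subset of
#'   the background; a warning is emitted otherwise).
#' @param elements Named list of interval tibbles (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @return Tibble per element: `element`, `odds_ratio`, `p`, `proportion`,
#'   and the 2x2 cells `n_qtl_in`, `n_qtl_out`, `n_bg_in`, `n_bg_out`.
#' @export
element_enrichment <- function(variants, qtl_ids, elements) {
  qtl_ids <- unique(qtl_ids)
  if (!all(qtl_ids %in% variants$variant_id)) {
    warn("some QTL variants are absent from the background set")
  }
  is_qtl <- variants$variant_id %in% qtl_ids
  rows <- list()
  for (nm in names(elements)) {
    el <- as_tibble(elements[[nm]])
    if (nrow(el) == 0) {
      warn(paste("element set", nm, "is empty; skipped"))
      next
    }
    inside <- overlaps_elements(variants$chrom, variants$pos, el)
    a <- sum(is_qtl & inside)
    b <- sum(is_qtl & !inside)
    cc <- sum(!is_qtl & inside)
    d <- sum(!is_qtl & !inside)
    p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
    rows[[nm]] <- tibble(
      element = nm,
      odds_ratio = (a * d) / (b * cc),
      p = p,
      proportion = a / sum(is_qtl),
      n_qtl_in = a, n_qtl_out = b, n_bg_in = cc, n_bg_out = d
    )
  }
  bind_rows(rows)
}

# point-in-interval test against a (chrom, start, end) table, 0-based half-open
overlaps_elements <- function(chrom, pos, el) {
  out <- logical(length(pos))
  for (ch in unique(el$chrom)) {
    q <- which(chrom == ch)
    if (!length(q)) next
    sub <- el[el$chrom == ch, ]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    qr <- IRanges::IRanges(start = pos[q] + 1L, width = 1L)
    hit <- IRanges::overlapsAny(qr, ir)
    out[q] <- hit
  }
  out
}
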