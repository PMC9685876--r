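#' Co-expression contrast of mediated, colocalized-only and random gene pairs
#'
#' For each gene pair the statistic is the absolute Pearson correlation of the
#' two genes' expression across samples. Random pairs are drawn by matching
#' each mediated pair's genes on mean-expression decile, so the random group
#' shares the real pairs' expression-level profile. Groups are compared with
#' two-sample Wilcoxon rank-sum tests (mediated vs colocalized-only, mediated
#' vs random, colocalized-only vs random).
#'
#' @param mediation_pairs Tibble with `cis_gene`, `trans_gene` (pairs with
#'   mediation evidence).
#' @param coloc_only_pairs Tibble with `cis_gene`, `trans_gene` (colocalized
#'   but not mediated).
#' @param expr An `expression_matrix`.
#' @param n_random Number of matched random pairs to draw.
#' @param n_bins Number of expression-level bins used for matching (deciles).
#' @param seed Seed for the random draws.
#' @return A `coexpression_contrast`: list with `observations` (tibble:
#'   `group`, `abs_r`) and `tests` (tibble: `group1`, `group2`, `p`,
#'   `median1`, `median2`).
#' @export
coexpression_contrast <- function(mediation_pairs, coloc_only_pairs, expr,
                                  n_random = 1000, n_bins = 10, seed = 1) {
  vals <- expr$values
  pair_abs_r <- function(pairs) {
    keep <- pairs$cis_gene %in% rownames(vals) & pairs$trans_gene %in% rownames(vals)
    if (any(!keep)) warn("pairs with missing genes dropped")
    pairs <- pairs[keep, , drop = FALSE]
    ok <- vapply(seq_len(nrow(pairs)), function(i) {
      sd(vals[pairs$cis_gene[i], ]) > 0 && sd(vals[pairs$trans_gene[i], ]) > 0
    }, logical(1))
    if (any(!ok)) warn("pairs with constant genes dropped")
    pairs <- pairs[ok, , drop = FALSE]
    vapply(seq_len(nrow(pairs)), function(i) {
      abs(cor(vals[pairs$cis_gene[i], ], vals[pairs$trans_gene[i], ]))
    }, numeric(1))
  }
  med_r <- pair_abs_r(mediation_pairs)
  col_r <- pair_abs_r(coloc_only_pairs)

  means <- rowMeans(vals)
  bins <- dplyr::ntile(means, n_bins)
  names(bins) <- rownames(vals)
  by_bin <- split(rownames(vals), bins)
  ref <- mediation_pairs
  rand_r <- with_seed_if(seed, {
    vapply(seq_len(n_random), function(k) {
      i <- ((k - 1L) %% nrow(ref)) + 1L
      g1 <- sample(by_bin[[as.character(bins[[ref$cis_gene[i]]])]], 1L)
      g2 <- sample(by_bin[[as.character(bins[[ref$trans_gene[i]]])]], 1L)
      while (g2 == g1) {
        g2 <- sample(by_bin[[as.character(bins[[ref$trans_gene[i]]])]], 1L)
      }
      abs(cor(vals[g1, ], vals[g2, ]))
    }, numeric(1))
  })

  obs <- bind_rows(
    tibble(group = "mediated", abs_r = med_r),
    tibble(group = "coloc_only", abs_r = col_r),
    tibble(group = "random", abs_r = rand_r)
  )
  cmp <- function(g1, g2) {
    x <- obs$abs_r[obs$group == g1]
    y <- obs$abs_r[obs$group == g2]
    p <- if (length(x) && length(y)) {
      wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
    } else NA_real_
    tibble(group1 = g1, group2 = g2, p = p,
           median1 = median(x), median2 = median(y))
  }
  tests <- bind_rows(
    cmp("mediated", "coloc_only"),
    cmp("mediated", "random"),
    cmp("coloc_only", "random")
  )
  structure(list(observations = obs, tests = tests),
            class = "coexpression_contrast")
}

#' @export
print.coexpression_contrast <- function(x, ...) {
  cat("<coexpression_contrast>\n")
  print(x$tests)
  invisible(x)
}

#' Effect-size contrast between eGene categories
#'
#' Compares the absolute effect-size distributions of gene groups (e.g. trans
#' eGenes that are also cis eGenes, trans-only eGenes, and cis mediators) with
#' two-sample Kolmogorov--Smirnov tests for every group pair.
#'
#' @param groups Tibble with `gene_id`, `group`.
#' @param effect_sizes Tibble with `gene_id`, `beta` (per-gene effect sizes;
#'   absolute values are compared).
#' @param min_size Groups smaller than this are flagged low power.
#' @return Tibble per group pair: `group1`, `group2`, `D`, `p`, `n1`, `n2`,
#'   `low_power`.
#' @export
effect_size_contrast <- function(groups, effect_sizes, min_size = 5) {
  dat <- inner_join(groups, effect_sizes, by = "gene_id") |>
    mutate(abs_beta = abs(.data$beta))
  gs <- split(dat$abs_beta, dat$group)
  if (sum(lengths(gs) > 0) < 2) abort("need >= 2 non-empty groups")
  small <- names(gs)[lengths(gs) < min_size]
  if (length(small)) {
    warn(paste("low-power groups (<", min_size, "values):",
               paste(small, collapse = ", ")))
  }
  nms <- names(gs)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) if (i < j) {
    ks <- suppressWarnings(ks.test(gs[[i]], gs[[j]]))
    rows[[length(rows) + 1L]] <- tibble(
      group1 = nms[i], group2 = nms[j],
      D = unname(ks$statistic), p = ks$p.value,
      n1 = length(gs[[i]]), n2 = length(gs[[j]]),
      low_power = nms[i] %in% small || nms[j] %in% small
    )
  }
  bind_rows(rows)
}

#' Network-centrality (kME) contrast between eGene groups
#'
#' Two-sample Wilcoxon rank-sum tests of module-membership (kME) values
#' between gene groups (e.g. disease trans-eGenes vs cis-eGenes vs all
#' expressed genes). kME values are supplied externally; genes without a value
#' are dropped with a warning.
#'
#' @param kme_table Tibble with `gene_id`, `kme`.
#' @param groups Tibble with `gene_id`, `group`.
#' @return Tibble per group pair: `group1`, `group2`, `p`, `median1`,
#'   `median2`, `n1`, `n2`.
#' @export
centrality_contrast <- function(kme_table, groups) {
  dat <- left_join(groups, kme_table, by = "gene_id")
  if (anyNA(dat$kme)) {
    warn(sprintf("%d gene(s) without kME dropped", sum(is.na(dat$kme))))
    dat <- dat[!is.na(dat$kme), ]
  }
  gs <- split(dat$kme, dat$group)
  if (length(gs) < 2) abort("need >= 2 non-empty groups")
  nms <- names(gs)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) if (i < j) {
    wt <- suppressWarnings(wilcox.test(gs[[i]], gs[[j]]))
    rows[[length(rows) + 1L]] <- tibble(
      group1 = nms[i], group2 = nms[j], p = wt$p.value,
      median1 = median(gs[[i]]), median2 = median(gs[[j]]),
      n1 = length(gs[[i]]), n2 = length(gs[[j]])
    )
  }
  bind_rows(rows)
}
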