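#' Detect trans-eQTL hotspots
#'
#' Groups an LD-pruned trans-eQTL list by variant; variants associated with at
#' least `min_targets` distinct trans genes are hotspots. Duplicate
#' (variant, gene) records count once.
#'
#' @param qtl_list Trans-eQTL tibble (`variant_id`, `gene_id`), LD-pruned so
#'   each eSNP is an independent signal.
#' @param min_targets Minimum number of distinct target genes (default 3).
#' @return Tibble per hotspot: `variant_id`, `n_targets`, `target_genes`
#'   (list column).
#' @export
detect_hotspots <- function(qtl_list, min_targets = 3) {
  if (nrow(qtl_list) == 0) {
    return(tibble(variant_id = character(), n_targets = integer(),
                  target_genes = list()))
  }
  qtl_list |>
    distinct(.data$variant_id, .data$gene_id) |>
    group_by(.data$variant_id) |>
    summarise(n_targets = dplyr::n(),
              target_genes = list(.data$gene_id), .groups = "drop") |>
    filter(.data$n_targets >= min_targets) |>
    arrange(dplyr::desc(.data$n_targets), .data$variant_id)
}

#' Test hotspot target co-regulation against expression-matched nulls
#'
#' For each hotspot, the observed statistic is the mean absolute Pearson
#' correlation over all pairs of its target genes. The null resamples
#' `n_random` gene sets of the same size, each target replaced by a random
#' gene from the same mean-expression bin (deciles by default), so every null
#' draw preserves the targets' expression-level composition exactly. The
#' empirical p is `(1 + #{null mean >= observed}) / (n_random + 1)`. A pooled
#' summary (mean over hotspots vs the null of per-draw means over hotspots)
#' is attached as attribute `pooled_p`.
#'
#' @param hotspots Tibble from [detect_hotspots()].
#' @param expr An `expression_matrix`.
#' @param n_random Number of null gene sets per hotspot.
#' @param n_bins Number of expression-level matching bins.
#' @param seed Seed for the resampling.
#' @return The hotspot tibble with `mean_abs_r`, `empirical_p`, `null_quantile`
#'   columns; attribute `pooled_p`.
#' @export
coregulation_test <- function(hotspots, expr, n_random = 1000, n_bins = 10,
                              seed = 1) {
  vals <- expr$values
  ok <- vapply(hotspots$target_genes, function(g) all(g %in% rownames(vals)),
               logical(1))
  if (any(!ok)) {
    warn(sprintf("%d hotspot(s) with targets missing from expression dropped",
                 sum(!ok)))
    hotspots <- hotspots[ok, , drop = FALSE]
  }
  if (nrow(hotspots) == 0) {
    out <- mutate(hotspots, mean_abs_r = numeric(0), empirical_p = numeric(0),
                  null_quantile = numeric(0))
    return(structure(out, pooled_p = NA_real_))
  }
  mean_abs_cor <- function(genes) {
    cm <- cor(t(vals[genes, , drop = FALSE]))
    mean(abs(cm[upper.tri(cm)]))
  }
  bins <- dplyr::ntile(rowMeans(vals), n_bins)
  names(bins) <- rownames(vals)
  by_bin <- split(rownames(vals), bins)

  obs <- vapply(hotspots$target_genes, mean_abs_cor, numeric(1))
  null_means <- with_seed_if(seed, {
    vapply(seq_len(n_random), function(b) {
      vapply(hotspots$target_genes, function(genes) {
        draw <- vapply(genes, function(g) {
          sample(by_bin[[as.character(bins[[g]])]], 1L)
        }, character(1))
        # matching guarantee: same bin multiset as the targets
        stopifnot(identical(sort(unname(bins[draw])), sort(unname(bins[genes]))))
        mean_abs_cor(unname(draw))
      }, numeric(1))
    }, numeric(nrow(hotspots)))
  })
  null_means <- matrix(null_means, nrow = nrow(hotspots))
  emp_p <- vapply(seq_len(nrow(hotspots)), function(i) {
    (1 + sum(null_means[i, ] >= obs[i])) / (n_random + 1)
  }, numeric(1))
  nq <- vapply(seq_len(nrow(hotspots)), function(i) {
    mean(null_means[i, ] < obs[i])
  }, numeric(1))
  pooled_p <- (1 + sum(colMeans(null_means) >= mean(obs))) / (n_random + 1)

  out <- hotspots |>
    mutate(mean_abs_r = obs, empirical_p = emp_p, null_quantile = nq)
  structure(out, pooled_p = pooled_p)
}
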