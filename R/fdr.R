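#' Pooled Benjamini--Hochberg FDR over association records
#'
#' Computes BH q-values over the pooled nominal p-values of all records and
#' keeps records with `q < alpha`. In the standard pipeline this runs on the
#' full trans record list and [ld_prune()] reduces the significant candidates
#' to independent signals afterwards; running BH on an already greedily
#' pruned list is anti-conservative because pruning keeps per-clump minima.
#'
#' @param records Association tibble.
#' @param alpha FDR threshold (the study's working lists use 0.25 and 0.05).
#' @return Tibble of retained records with a `q` column; attributes `scheme`
#'   (`"pooled"`) and `alpha` record the correction applied.
#' @export
pooled_fdr <- function(records, alpha = 0.25) {
  if (nrow(records) == 0) {
    out <- mutate(records, q = numeric(0))
  } else {
    out <- mutate(records, q = p.adjust(.data$p, method = "BH")) |>
      filter(.data$q < alpha)
  }
  structure(out, scheme = "pooled", alpha = alpha)
}

#' Hierarchical gene-level FDR (Sidak then BH)
#'
#' Per gene, the minimum nominal p over its `m` tests is corrected with the
#' Sidak formula `1 - (1 - p_min)^m`; BH is then applied across genes and
#' genes with `q < alpha` are called eGenes.
#'
#' @param records Association tibble.
#' @param tests_per_gene Named vector or tibble (`gene_id`, `m`) giving the
#'   number of tests per gene; every gene with records must be present with
#'   `m >= 1`.
#' @param alpha Gene-level FDR threshold.
#' @return Tibble per gene: `gene_id`, `p_min`, `m`, `p_corrected`, `q`,
#'   `egene`.
#' @export
hierarchical_gene_fdr <- function(records, tests_per_gene, alpha = 0.25) {
  if (is.data.frame(tests_per_gene)) {
    tests_per_gene <- setNames(tests_per_gene$m, tests_per_gene$gene_id)
  }
  per_gene <- records |>
    group_by(.data$gene_id) |>
    summarise(p_min = min(.data$p), .groups = "drop")
  m <- tests_per_gene[per_gene$gene_id]
  if (anyNA(m) || any(m < 1)) {
    abort("every gene with records needs a positive test count")
  }
  per_gene |>
    mutate(
      m = as.numeric(m),
      p_corrected = sidak(.data$p_min, .data$m),
      q = p.adjust(.data$p_corrected, method = "BH"),
      egene = .data$q < alpha
    )
}

# 1 - (1 - p)^m computed stably for small p
sidak <- function(p, m) -expm1(m * log1p(-p))

#' Permutation-based gene-level FDR
#'
#' For each gene, the observed minimum nominal p over its testable variants is
#' compared with minima from `n_perm` sample-label permutations of the
#' covariate-residualized expression (one shared permutation per iteration
#' across genes, so each permutation costs one matrix product). The empirical
#' gene-level p is `(1 + #{perm min-p <= observed}) / (n_perm + 1)`; BH is
#' applied across genes, and for significant genes all associations at or
#' below the gene's `alpha`-quantile permutation threshold are reported.
#'
#' @inheritParams nominal_scan
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Gene-level FDR threshold.
#' @param seed Seed for the permutation stream.
#' @return List with `genes` (tibble: `gene_id`, `p_min`, `empirical_p`, `q`,
#'   `egene`, `p_threshold`) and `records` (associations of significant genes
#'   passing their gene's threshold, with `scheme = "permutation"`).
#' @export
permutation_gene_fdr <- function(expr, genotypes, covariates = NULL,
                                 mode = c("trans", "cis"), n_perm = 1000,
                                 alpha = 0.25, seed = 1,
                                 cis_window_bp = 1e6, trans_min_bp = 5e6) {
  mode <- match.arg(mode)
  if (n_perm < 100) abort("n_perm must be >= 100")
  if (n_perm < 1 / alpha - 1) {
    warn("n_perm is too small to resolve the requested alpha")
  }
  eng <- scan_engine(expr, genotypes, covariates)
  mask <- scan_mask(expr, genotypes, mode, cis_window_bp, trans_min_bp)
  mask[eng$mono, ] <- FALSE
  pmat <- 2 * pt(-abs(eng$t), eng$df)
  pmat[!mask] <- NA_real_
  obs_min <- apply(pmat, 2, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))

  Yr <- residualize(expr$values, covariates)
  Gr <- t(residualize(t(genotypes$dosage), covariates))
  ssy <- rowSums(Yr^2)
  ssg <- colSums(Gr^2)
  n_genes <- nrow(Yr)
  count_beat <- numeric(n_genes)
  perm_min <- matrix(NA_real_, nrow = n_perm, ncol = n_genes)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(ncol(Yr))
      r <- crossprod(Gr, t(Yr[, perm, drop = FALSE])) / sqrt(outer(ssg, ssy))
      r <- pmin(pmax(r, -1), 1)
      pp <- 2 * pt(-abs(r * sqrt(eng$df / pmax(1 - r^2, .Machine$double.eps))), eng$df)
      pp[!mask] <- NA_real_
      pm <- apply(pp, 2, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
      perm_min[b, ] <- pm
      count_beat <- count_beat + as.numeric(!is.na(pm) & !is.na(obs_min) & pm <= obs_min)
    }
  })
  tested <- !is.na(obs_min)
  genes <- tibble(
    gene_id = expr$genes$gene_id,
    p_min = obs_min,
    empirical_p = ifelse(tested, (1 + count_beat) / (n_perm + 1), NA_real_),
    p_threshold = vapply(seq_len(n_genes), function(j) {
      if (!tested[j]) return(NA_real_)
      quantile(perm_min[, j], probs = alpha, type = 1, na.rm = TRUE)
    }, numeric(1))
  ) |> filter(tested)
  genes$q <- p.adjust(genes$empirical_p, method = "BH")
  genes$egene <- genes$q < alpha

  recs <- nominal_scan(expr, genotypes, covariates, mode = mode,
                       cis_window_bp = cis_window_bp, trans_min_bp = trans_min_bp)
  sig <- genes |> filter(.data$egene)
  records <- recs |>
    inner_join(sig[, c("gene_id", "p_threshold", "q")], by = "gene_id") |>
    filter(.data$p <= .data$p_threshold)
  structure(list(genes = genes, records = records),
            scheme = "permutation", alpha = alpha)
}

#' Split-half replication of the trans scan
#'
#' Randomly splits the cohort into two disjoint equal folds, runs the full
#' trans pipeline (scan, pooled FDR, LD pruning) independently in each, and
#' reports the overlap of the called (variant, gene) pairs as
#' `|A intersect B| / min(|A|, |B|)` (intersection over the smaller list).
#'
#' @inheritParams nominal_scan
#' @param alpha Pooled FDR threshold used in each fold.
#' @param r2_threshold LD-pruning threshold used in each fold.
#' @param seed Seed for the random split.
#' @param folds Optional list of two disjoint sample-index vectors overriding
#'   the random split (e.g. for batch-stratified folds).
#' @return One-row tibble: `overlap`, `n_fold1`, `n_fold2`, `n_shared`.
#' @export
split_half_replication <- function(expr, genotypes, covariates = NULL,
                                   alpha = 0.05, r2_threshold = 0.6, seed = 1,
                                   folds = NULL,
                                   cis_window_bp = 1e6, trans_min_bp = 5e6) {
  n <- ncol(expr$values)
  if (n < 4) abort("too few samples to split")
  if (is.null(folds)) {
    idx <- withr::with_seed(as.integer(seed), sample.int(n))
    half <- floor(n / 2)
    folds <- list(sort(idx[seq_len(half)]), sort(idx[(half + 1):(2 * half)]))
  }
  if (length(intersect(folds[[1]], folds[[2]])) != 0) {
    abort("folds must be disjoint")
  }

  call_fold <- function(keep) {
    ex <- expression_matrix(expr$values[, keep, drop = FALSE], expr$genes)
    gt <- new_genotype_matrix(genotypes$dosage[keep, , drop = FALSE],
                              genotypes$variants)
    cv <- if (is.null(covariates)) NULL else {
      X <- unclass(covariates)[keep, , drop = FALSE]
      X <- scale(X, center = TRUE, scale = FALSE)
      attr(X, "scaled:center") <- NULL
      structure(X, class = class(covariates))
    }
    recs <- nominal_scan(ex, gt, cv, mode = "trans",
                         cis_window_bp = cis_window_bp,
                         trans_min_bp = trans_min_bp)
    ld_prune(pooled_fdr(recs, alpha), gt, r2_threshold = r2_threshold)
  }
  a <- call_fold(folds[[1]])
  b <- call_fold(folds[[2]])
  pa <- paste(a$variant_id, a$gene_id)
  pb <- paste(b$variant_id, b$gene_id)
  shared <- length(intersect(pa, pb))
  denom <- min(length(pa), length(pb))
  tibble(
    overlap = if (denom == 0) 0 else shared / denom,
    n_fold1 = length(pa), n_fold2 = length(pb), n_shared = shared
  )
}
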