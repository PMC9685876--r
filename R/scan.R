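#' @useDynLib transqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Matrix association engine (MatrixEQTL-style). Residualizes expression and
# dosage against [1, X] once (Frisch-Waugh), then converts residual
# correlations into OLS t statistics for the dosage coefficient:
#   t = r * sqrt(df / (1 - r^2)),  df = n - ncol(X) - 2  (X without intercept)
#   beta = r * s_y / s_g  on residual scales,  se = beta / t.
# Returns per-pair matrices (variants x genes).
scan_engine <- function(expr, genotypes, covariates = NULL) {
  Y <- expr$values
  D <- genotypes$dosage
  assert_samples_aligned(colnames(Y), rownames(D), "expression and genotypes")
  if (!is.null(covariates)) {
    assert_samples_aligned(colnames(Y), rownames(unclass(covariates)),
                           "expression and covariates")
  }
  n <- ncol(Y)
  k <- if (is.null(covariates)) 0L else ncol(unclass(covariates))
  df <- n - k - 2L
  if (df <= 0) abort("zero residual degrees of freedom")

  mono <- apply(D, 2, function(x) min(x) == max(x))
  if (any(mono)) {
    inform(sprintf("skipping %d monomorphic variant(s)", sum(mono)))
  }
  Yr <- residualize(Y, covariates)                    # genes x samples
  Gr <- t(residualize(t(D), covariates))              # samples x variants
  ssy <- rowSums(Yr^2)
  ssg <- colSums(Gr^2)
  cross <- crossprod(Gr, t(Yr))                       # variants x genes
  denom <- sqrt(outer(ssg, ssy))
  r <- cross / denom
  r[mono, ] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  beta <- cross / ssg
  se <- sqrt(outer(1 / ssg, ssy) * pmax(1 - r^2, 0) / df)
  se[mono, ] <- NA_real_
  list(r = r, t = tstat, beta = beta, se = se, df = df, mono = mono)
}

# variants x genes logical mask of testable pairs for a mode
scan_mask <- function(expr, genotypes, mode, cis_window_bp, trans_min_bp) {
  vtab <- genotypes$variants
  gtab <- expr$genes
  same_chrom <- outer(vtab$chrom, gtab$chrom, "==")
  dist <- abs(outer(vtab$pos, gtab$tss, "-"))
  if (mode == "cis") {
    same_chrom & dist <= cis_window_bp
  } else {
    (!same_chrom) | (same_chrom & dist > trans_min_bp)
  }
}

#' Nominal cis/trans association scan
#'
#' For every testable (variant, gene) pair, fits ordinary least squares of the
#' normalized expression on the dosage plus covariates and an intercept, and
#' reports the two-sided t-test on the dosage coefficient. A pair is `cis`
#' when the variant lies within `cis_window_bp` of the gene's TSS on the same
#' chromosome, and `trans` when it lies on a different chromosome or more than
#' `trans_min_bp` from the TSS; pairs in between are not tested in either
#' mode. Monomorphic variants are skipped with a message.
#'
#' @param expr A normalized `expression_matrix`.
#' @param genotypes A `genotype_matrix` with samples aligned to `expr`.
#' @param covariates A `covariate_matrix` or `NULL`.
#' @param mode `"trans"` or `"cis"`.
#' @param cis_window_bp Cis window around the TSS (default 1 Mb).
#' @param trans_min_bp Same-chromosome exclusion distance for trans (5 Mb).
#' @return Tibble of association records: `variant_id`, `gene_id`, `beta`,
#'   `se`, `p`, `df`, `label`.
#' @export
nominal_scan <- function(expr, genotypes, covariates = NULL,
                         mode = c("trans", "cis"),
                         cis_window_bp = 1e6, trans_min_bp = 5e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(genotypes, "genotype_matrix"))
  eng <- scan_engine(expr, genotypes, covariates)
  mask <- scan_mask(expr, genotypes, mode, cis_window_bp, trans_min_bp)
  mask[eng$mono, ] <- FALSE
  idx <- which(mask)
  if (!length(idx)) {
    return(tibble(variant_id = character(), gene_id = character(),
                  beta = numeric(), se = numeric(), p = numeric(),
                  df = integer(), label = character()))
  }
  vi <- row(mask)[idx]
  gi <- col(mask)[idx]
  tval <- eng$t[idx]
  tibble(
    variant_id = genotypes$variants$variant_id[vi],
    gene_id = expr$genes$gene_id[gi],
    beta = eng$beta[idx],
    se = eng$se[idx],
    p = 2 * pt(-abs(tval), eng$df),
    df = eng$df,
    label = mode
  )
}

#' Remove associations between cross-mappable locus pairs
#'
#' Drops records whose (variant locus, gene locus) pair appears in an
#' unordered blacklist of cross-mapping genomic locus pairs, as produced by
#' RNA-seq mappability screens.
#'
#' @param records Association tibble from [nominal_scan()].
#' @param blacklist Tibble with columns `locus_a`, `locus_b` holding unordered
#'   pairs of locus labels; records are matched by `variant_locus` and
#'   `gene_locus` columns if present, else by `variant_id` / `gene_id`.
#' @return The filtered records; the number removed is reported via a message.
#' @export
cross_map_filter <- function(records, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(records)
  if (!all(c("locus_a", "locus_b") %in% names(blacklist))) {
    abort("blacklist needs columns locus_a, locus_b")
  }
  va <- if ("variant_locus" %in% names(records)) records$variant_locus else records$variant_id
  ga <- if ("gene_locus" %in% names(records)) records$gene_locus else records$gene_id
  key <- paste(pmin(va, ga), pmax(va, ga))
  bad_key <- paste(pmin(blacklist$locus_a, blacklist$locus_b),
                   pmax(blacklist$locus_a, blacklist$locus_b))
  drop <- key %in% bad_key
  if (any(drop)) inform(sprintf("cross-mappability filter removed %d record(s)", sum(drop)))
  records[!drop, , drop = FALSE]
}

#' Greedy LD pruning of association records
#'
#' Visits records in ascending nominal p (ties broken by variant id) and keeps
#' a record unless its variant exceeds the squared-correlation threshold with
#' a different variant already kept on the same chromosome. By default the
#' greedy pass runs within each gene's record list, so one variant can remain
#' the independent signal for several trans genes (the situation a hotspot
#' describes); `per_gene = FALSE` runs a single global pass in which records
#' of an already-kept variant are retained.
#'
#' @param records Association tibble.
#' @param genotypes A `genotype_matrix` covering all record variants.
#' @param r2_threshold Squared Pearson dosage correlation above which two
#'   variants are considered dependent (default 0.6).
#' @param per_gene Prune within each gene's records (default) or globally.
#' @return The pruned records tibble.
#' @export
ld_prune <- function(records, genotypes, r2_threshold = 0.6, per_gene = TRUE) {
  if (nrow(records) == 0) return(records)
  vtab <- genotypes$variants
  miss <- setdiff(unique(records$variant_id), vtab$variant_id)
  if (length(miss)) abort(paste("no dosages for variants:", paste(miss, collapse = ", ")))

  used <- vtab$variant_id[vtab$variant_id %in% records$variant_id]
  chrom_of <- vtab$chrom[match(used, vtab$variant_id)]
  chroms <- sort(unique(chrom_of))
  r2_list <- vector("list", length(chroms))
  col_in_chrom <- integer(length(used))
  for (ci in seq_along(chroms)) {
    on_c <- which(chrom_of == chroms[ci])
    Dc <- genotypes$dosage[, used[on_c], drop = FALSE]
    r2_list[[ci]] <- cor(Dc)^2
    col_in_chrom[on_c] <- seq_along(on_c)
  }
  v_idx <- match(records$variant_id, used)
  rec_chrom <- match(chrom_of[v_idx], chroms)
  rec_col <- col_in_chrom[v_idx]

  prune_group <- function(rows) {
    ord <- rows[order(records$p[rows], records$variant_id[rows])]
    keep <- greedy_ld_prune(match(ord, rows), rec_chrom[rows], rec_col[rows],
                            r2_list, r2_threshold)
    rows[keep]
  }
  kept_rows <- if (per_gene) {
    groups <- split(seq_len(nrow(records)), records$gene_id)
    sort(unlist(lapply(groups, prune_group), use.names = FALSE))
  } else {
    sort(prune_group(seq_len(nrow(records))))
  }
  records[kept_rows, , drop = FALSE]
}
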