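#' Assemble the covariate matrix for association scans
#'
#' Hidden expression factors are the top principal components of the
#' normalized expression matrix -- a deliberate surrogate for Bayesian hidden
#' factor models (PEER): both capture the dominant inter-sample covariation
#' that confounds trans scans. Genotype population structure enters as the top
#' principal components of the standardized dosage matrix. Categorical sample
#' covariates (e.g. sex, study) are expanded to treatment-coded indicator
#' columns. All columns are centered; the assembled matrix must be full column
#' rank once an intercept is added.
#'
#' The effective number of expression factors is capped at
#' `floor(n_samples / 10)` to avoid overfitting small cohorts.
#'
#' @param expr A normalized `expression_matrix`.
#' @param genotypes A `genotype_matrix` (only needed when `n_pcs > 0`).
#' @param n_factors Number of hidden expression factors requested.
#' @param n_pcs Number of genotype principal components.
#' @param sample_table Optional tibble with a `sample_id` column plus
#'   categorical/numeric covariates (e.g. `sex`, `study`).
#' @return A `covariate_matrix`: samples x covariates numeric matrix with
#'   sample rownames and labelled columns.
#' @export
build_covariates <- function(expr, genotypes = NULL, n_factors = 0, n_pcs = 0,
                             sample_table = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  samples <- colnames(expr$values)
  n <- length(samples)
  if (n_factors >= n || n_pcs >= n) {
    abort("numbers of factors/PCs must be smaller than the sample size")
  }
  n_factors <- min(n_factors, floor(n / 10))
  cols <- list()

  if (n_factors > 0) {
    pca <- prcomp(t(expr$values), center = TRUE, scale. = FALSE)
    fac <- pca$x[, seq_len(n_factors), drop = FALSE]
    colnames(fac) <- paste0("factor", seq_len(n_factors))
    cols$factors <- fac
  }
  if (n_pcs > 0) {
    if (is.null(genotypes)) abort("genotype PCs requested without genotypes")
    assert_samples_aligned(rownames(genotypes$dosage), samples,
                           "expression and genotypes")
    sds <- apply(genotypes$dosage, 2, sd)
    std <- scale(genotypes$dosage[, sds > 0, drop = FALSE])
    pca <- prcomp(std, center = FALSE, scale. = FALSE)
    pcs <- pca$x[, seq_len(n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("geno_pc", seq_len(n_pcs))
    cols$pcs <- pcs
  }
  if (!is.null(sample_table)) {
    sample_table <- as_tibble(sample_table)
    if (!"sample_id" %in% names(sample_table)) {
      abort("`sample_table` needs a sample_id column")
    }
    sample_table <- sample_table[match(samples, sample_table$sample_id), ]
    for (nm in setdiff(names(sample_table), "sample_id")) {
      v <- sample_table[[nm]]
      if (is.numeric(v)) {
        m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      } else {
        v <- factor(v)
        if (nlevels(v) < 2) next
        m <- stats::model.matrix(~v)[, -1, drop = FALSE]
        colnames(m) <- paste0(nm, "_", levels(v)[-1])
      }
      cols[[nm]] <- m
    }
  }
  if (!length(cols)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- do.call(cbind, unname(cols))
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  rownames(X) <- samples
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    abort(paste("covariate matrix is rank deficient; collinear columns:",
                paste(colnames(X)[dropped], collapse = ", ")))
  }
  structure(X, class = c("covariate_matrix", "matrix", "array"))
}

#' Residualize a samples-in-columns matrix against covariates
#'
#' Projects each row of `m` (genes x samples or variants in columns after
#' transpose) onto the orthogonal complement of `[1, X]`. Residualizing twice
#' equals residualizing once (a true projection).
#'
#' @param m Numeric matrix with samples in columns.
#' @param covariates A `covariate_matrix` or `NULL` (intercept only).
#' @return Matrix of residuals, same shape.
#' @export
residualize <- function(m, covariates = NULL) {
  n <- ncol(m)
  X <- cbind(intercept = rep(1, n), unclass(covariates))
  Q <- qr.Q(qr(X))
  m - (m %*% Q) %*% t(Q)
}
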