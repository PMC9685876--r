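#' Remove genes detected in too few samples
#'
#' Lowly expressed genes that are zero in (almost) every sample produce
#' spurious associations after rank-based normalization, so they are dropped
#' before any scan.
#'
#' @param expr An `expression_matrix`.
#' @param min_nonzero_samples Minimum number of samples with a nonzero value a
#'   gene must have to survive (>= 1).
#' @return The filtered `expression_matrix`, survivor order preserved.
#' @export
filter_genes <- function(expr, min_nonzero_samples = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  assert_count(min_nonzero_samples, "min_nonzero_samples")
  keep <- rowSums(expr$values != 0) >= min_nonzero_samples
  if (!any(keep)) abort("no genes survive the detection filter")
  expression_matrix(expr$values[keep, , drop = FALSE], expr$genes[keep, ])
}

#' Quantile-normalize expression across samples
#'
#' Forces every sample (column) onto the common reference distribution: the
#' mean of sorted values across samples; ties within a sample receive the mean
#' of the reference values they span (the `limma` tie rule).
#'
#' @param expr An `expression_matrix` with >= 2 samples.
#' @return The normalized `expression_matrix`.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 2) abort("quantile normalization needs >= 2 samples")
  values <- limma::normalizeQuantiles(expr$values, ties = TRUE)
  dimnames(values) <- dimnames(expr$values)
  expression_matrix(values, expr$genes)
}

#' Rank-based inverse normal transform
#'
#' Maps the value with (average) rank `k` among `n` to
#' `qnorm((k - offset) / (n - 2 * offset + 1))`; the default Blom offset 3/8
#' gives `qnorm((k - 3/8) / (n + 1/4))`. Applied per gene across samples.
#'
#' @param values Numeric vector (one gene across samples), `n >= 2`, not all
#'   identical.
#' @param offset Rank offset; 3/8 (Blom) by default.
#' @return Numeric vector of standard-normal scores, monotone in input ranks.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  if (length(values) < 2) abort("inverse normal transform needs n >= 2")
  if (length(unique(values)) == 1L) {
    abort("all values identical: ranks undefined for inverse normal transform")
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (length(values) - 2 * offset + 1))
}

#' GTEx-style expression normalization
#'
#' Convenience composition used before every scan: detection filter, quantile
#' normalization across samples, then per-gene inverse normal transform.
#'
#' @inheritParams filter_genes
#' @inheritParams inverse_normal_transform
#' @return A normalized `expression_matrix` (each gene standard normal in
#'   rank).
#' @export
normalize_expression <- function(expr, min_nonzero_samples = 1, offset = 3 / 8) {
  expr <- filter_genes(expr, min_nonzero_samples)
  expr <- quantile_normalize(expr)
  values <- t(apply(expr$values, 1, inverse_normal_transform, offset = offset))
  dimnames(values) <- dimnames(expr$values)
  expression_matrix(values, expr$genes)
}
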