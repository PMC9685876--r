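# Small builders and independent oracles shared across the suite.

toy_genotypes <- function(dosage, chrom = NULL, pos = NULL) {
  V <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("v%02d", seq_len(V))
  rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  genotype_matrix(dosage, tibble::tibble(
    variant_id = colnames(dosage),
    chrom = chrom %||% rep(1L, V),
    pos = pos %||% as.integer(seq_len(V) * 1000L)
  ))
}

toy_expression <- function(values, chrom = NULL, tss = NULL) {
  G <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(G))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  expression_matrix(values, tibble::tibble(
    gene_id = rownames(values),
    chrom = chrom %||% rep(1L, G),
    tss = tss %||% as.integer(seq_len(G) * 1000L),
    strand = "+"
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# columns with exact sample correlation matrix R, affinely mapped into [0, 2]
# (centered orthonormal basis x chol factor => cor(X) == R to machine precision)
correlated_columns <- function(R, n = 40) {
  k <- ncol(R)
  set.seed(20240915)
  A <- scale(matrix(rnorm(n * k), nrow = n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(A))
  X <- Q %*% chol(R) # X'X = U'U = R for the upper Cholesky factor U
  apply(X, 2, function(x) (x - min(x)) / (max(x) - min(x)) * 2)
}

# three columns with exact pairwise correlations (r_ab, r_bc, r_ac)
correlated_triplet <- function(r_ab, r_bc, r_ac, n = 40) {
  R <- matrix(c(1, r_ab, r_ac,
                r_ab, 1, r_bc,
                r_ac, r_bc, 1), nrow = 3)
  correlated_columns(R, n)
}

# closed-form simple OLS of y on g with intercept (normal equations)
hand_ols <- function(y, g) {
  n <- length(y)
  sxx <- sum((g - mean(g))^2)
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  res <- y - mean(y) - beta * (g - mean(g))
  df <- n - 2
  se <- sqrt(sum(res^2) / df / sxx)
  t <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(t), df), df = df)
}

# brute-force coloc: enumerate every single-causal configuration explicitly
brute_force_coloc <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  k <- length(labf1)
  b1 <- exp(labf1); b2 <- exp(labf2)
  h0 <- 1
  h1 <- p1 * sum(b1)
  h2 <- p2 * sum(b2)
  h3 <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    h3 <- h3 + p1 * p2 * b1[i] * b2[j]
  }
  h4 <- p12 * sum(b1 * b2)
  w <- c(h0, h1, h2, h3, h4)
  setNames(w / sum(w), paste0("pp", 0:4))
}

# two-sided Fisher p as an explicit hypergeometric tail sum
hypergeom_fisher_p <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# KS statistic by direct ECDF supremum enumeration
brute_force_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}
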