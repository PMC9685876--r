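#' Simulate GWAS summary statistics sharing causal variants with trans effects
#'
#' Planted causal variants (the truth's `gwas_causal_variants`) receive latent
#' z-scores of magnitude `N(gwas_causal_z, 1)` with random sign. Every other
#' variant's z is generated under the single-causal-variant summary-statistic
#' approximation: its expectation is the LD-weighted sum of causal z-scores
#' (empirical dosage correlation, same chromosome) and its residual standard
#' deviation is `sqrt(1 - max r^2)` with the causal set, i.e. the conditional
#' null given the causal signal. Standard errors follow the usual
#' `1 / sqrt(2 n maf (1 - maf))` scaling, `beta = z * se`, and p-values are
#' two-sided normal tails of `|z|`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param truth A `regulatory_truth` (or `NULL` for a pure-null trait).
#' @param config A [sim_config()].
#' @return A `gwas_summary` tibble: `variant_id`, `chrom`, `pos`, `beta`,
#'   `se`, `p`, `n`, with attribute `trait`.
#' @export
simulate_gwas_summary <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  causal <- if (is.null(truth)) character() else truth$gwas_causal_variants
  missing_causal <- setdiff(causal, genotypes$variants$variant_id)
  if (length(missing_causal)) {
    abort(paste("GWAS causal variants absent from genotypes:",
                paste(missing_causal, collapse = ", ")))
  }
  withr::with_seed(substream_seed(config$seed, "gwas"), {
    vtab <- genotypes$variants
    V <- nrow(vtab)
    z <- rnorm(V)
    if (length(causal)) {
      zc <- setNames((config$gwas_causal_z + rnorm(length(causal))) *
                       sample(c(-1, 1), length(causal), replace = TRUE), causal)
      mu <- numeric(V)
      shrink <- rep(1, V)
      for (cv in causal) {
        cchrom <- vtab$chrom[vtab$variant_id == cv]
        idx <- which(vtab$chrom == cchrom)
        r <- as.vector(cor(genotypes$dosage[, idx, drop = FALSE],
                           genotypes$dosage[, cv]))
        mu[idx] <- mu[idx] + r * zc[[cv]]
        shrink[idx] <- pmin(shrink[idx], sqrt(pmax(1 - r^2, 1e-4)))
      }
      z <- mu + shrink * z
    }
    se <- 1 / sqrt(2 * config$gwas_n * vtab$maf * (1 - vtab$maf))
    out <- tibble(
      variant_id = vtab$variant_id, chrom = vtab$chrom, pos = vtab$pos,
      beta = z * se, se = se, p = 2 * pnorm(-abs(z)), n = config$gwas_n
    )
    structure(out, class = c("gwas_summary", class(tibble())),
              trait = "synthetic_trait")
  })
}
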