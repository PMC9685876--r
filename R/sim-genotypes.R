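#' Simulate genotype dosages with block LD structure
#'
#' Draws biallelic genotypes under Hardy--Weinberg equilibrium with a
#' template-haplotype LD model: each block has one shared allele frequency and,
#' per haplotype, a latent template allele that every variant of the block
#' copies with probability `sqrt(ld_within_block_r)` (drawing a fresh allele
#' otherwise). Pairwise within-block dosage correlation therefore equals the
#' configured `ld_within_block_r` in expectation, `1` making all block
#' columns exact copies and `0` making them independent.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix`: list with `dosage` (samples x variants integer
#'   dosages in 0..2 with dimnames) and `variants` (tibble of `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `maf` with the folded empirical minor
#'   allele frequency; positions strictly increasing within chromosome).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(substream_seed(config$seed, "genotypes"), {
    n <- config$n_samples
    V <- config$n_variants_per_chrom
    r <- config$ld_within_block_r
    bases <- c("A", "C", "G", "T")
    dosage_cols <- vector("list", config$n_chromosomes)
    var_tabs <- vector("list", config$n_chromosomes)

    rho <- sqrt(r) # per-variant template-copy probability: pairwise corr = rho^2 = r
    for (chrom in seq_len(config$n_chromosomes)) {
      pos <- sort(sample.int(config$chrom_length_bp - 1L, V))
      block <- (seq_len(V) - 1L) %/% config$ld_block_size
      # one allele frequency per block: LD partners share their frequency,
      # which keeps the within-block correlation at the configured target
      maf_block <- runif(length(unique(block)),
                         config$maf_range[1], config$maf_range[2])
      maf <- maf_block[block + 1L]
      D <- matrix(0L, nrow = n, ncol = V)
      for (b in unique(block)) {
        idx <- which(block == b)
        m <- length(idx)
        hap <- matrix(0L, nrow = n, ncol = m)
        for (h in 1:2) {
          template <- rbinom(n, 1L, maf[idx[1]])
          copy <- matrix(runif(n * m) < rho, nrow = n)
          fresh <- matrix(rbinom(n * m, 1L, maf[idx[1]]), nrow = n)
          hap <- hap + ifelse(copy, template, fresh)
        }
        D[, idx] <- hap
      }
      # guard against monomorphic columns (possible at small n): redraw i.i.d.
      for (j in which(apply(D, 2, function(x) length(unique(x)) == 1L))) {
        for (try in 1:25) {
          D[, j] <- rbinom(n, 2L, maf[j])
          if (length(unique(D[, j])) > 1L) break
        }
      }
      af <- colMeans(D) / 2
      var_tabs[[chrom]] <- tibble(
        variant_id = sprintf("chr%d_v%04d", chrom, seq_len(V)),
        chrom = chrom, pos = as.integer(pos),
        ref = sample(bases, V, replace = TRUE),
        alt = NA_character_,
        maf = pmin(af, 1 - af)
      )
      var_tabs[[chrom]]$alt <- vapply(var_tabs[[chrom]]$ref, function(rf) {
        sample(setdiff(bases, rf), 1L)
      }, character(1))
      dosage_cols[[chrom]] <- D
    }

    dosage <- do.call(cbind, dosage_cols)
    variants <- bind_rows(var_tabs)
    rownames(dosage) <- sprintf("s%04d", seq_len(n))
    colnames(dosage) <- variants$variant_id
    new_genotype_matrix(dosage, variants)
  })
}

new_genotype_matrix <- function(dosage, variants) {
  structure(list(dosage = dosage, variants = as_tibble(variants)),
            class = "genotype_matrix")
}

#' Construct a genotype container from a dosage matrix
#'
#' @param dosage Samples x variants numeric matrix with dimnames; values in
#'   `[0, 2]`.
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (and optionally
#'   `ref`, `alt`, `maf`) matching the dosage columns.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  variants <- as_tibble(variants)
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$variant_id
  if (!identical(colnames(dosage), variants$variant_id)) {
    abort("dosage columns and variant table are not aligned")
  }
  if (anyNA(dosage) || min(dosage) < 0 || max(dosage) > 2) {
    abort("dosages must be complete and lie in [0, 2]")
  }
  if (!"maf" %in% names(variants)) {
    af <- colMeans(dosage) / 2
    variants$maf <- pmin(af, 1 - af)
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%04d", seq_len(nrow(dosage)))
  }
  new_genotype_matrix(dosage, variants)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)
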