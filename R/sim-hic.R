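#' Simulate a normalized interchromosomal Hi-C contact matrix
#'
#' Every interchromosomal bin pair at the configured resolution receives a
#' Poisson-distributed normalized contact frequency with mean
#' `hic_baseline_mean`; pairs listed in the truth's enriched set have their
#' mean multiplied by `hic_enrichment_factor`. Pairs are stored once in
#' canonical order (`chrom_a < chrom_b`) and are symmetric under swap by
#' construction of the lookup.
#'
#' @param truth A `regulatory_truth` (its `enriched_contact_pairs` drive the
#'   planted enrichment); may be `NULL` for a purely baseline matrix.
#' @param config A [sim_config()].
#' @return A `contact_matrix`: tibble of `chrom_a`, `bin_a`, `chrom_b`,
#'   `bin_b`, `freq` with attributes `resolution_bp` and `n_bins` per
#'   chromosome.
#' @export
simulate_contact_matrix <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(substream_seed(config$seed, "hic"), {
    res <- config$hic_resolution_bp
    n_bins <- as.integer(ceiling(config$chrom_length_bp / res))
    chroms <- seq_len(config$n_chromosomes)
    grid <- list()
    for (ca in chroms) for (cb in chroms) if (ca < cb) {
      grid[[length(grid) + 1L]] <- tibble(
        chrom_a = ca,
        bin_a = rep(seq_len(n_bins) - 1L, each = n_bins),
        chrom_b = cb,
        bin_b = rep(seq_len(n_bins) - 1L, times = n_bins)
      )
    }
    contacts <- if (length(grid)) bind_rows(grid) else
      tibble(chrom_a = integer(), bin_a = integer(),
             chrom_b = integer(), bin_b = integer())
    lambda <- rep(config$hic_baseline_mean, nrow(contacts))
    if (!is.null(truth) && nrow(truth$enriched_contact_pairs) > 0) {
      key <- paste(contacts$chrom_a, contacts$bin_a, contacts$chrom_b, contacts$bin_b)
      ek <- paste(truth$enriched_contact_pairs$chrom_a,
                  truth$enriched_contact_pairs$bin_a,
                  truth$enriched_contact_pairs$chrom_b,
                  truth$enriched_contact_pairs$bin_b)
      lambda[key %in% ek] <- lambda[key %in% ek] * config$hic_enrichment_factor
    }
    contacts$freq <- as.numeric(rpois(nrow(contacts), lambda))
    contact_matrix(contacts, resolution_bp = res,
                   n_bins = setNames(rep(n_bins, length(chroms)), chroms))
  })
}

#' Construct a contact-matrix container
#'
#' @param contacts Tibble of `chrom_a`, `bin_a`, `chrom_b`, `bin_b`, `freq`
#'   (interchromosomal pairs; stored in canonical order `chrom_a < chrom_b`).
#' @param resolution_bp Bin size in base pairs.
#' @param n_bins Optional named vector of bin counts per chromosome; inferred
#'   from the data when absent.
#' @return A `contact_matrix` tibble subclass.
#' @export
contact_matrix <- function(contacts, resolution_bp, n_bins = NULL) {
  contacts <- as_tibble(contacts)
  if (any(contacts$freq < 0)) abort("contact frequencies must be >= 0")
  if (any(contacts$chrom_a == contacts$chrom_b)) {
    abort("contact container stores interchromosomal pairs only")
  }
  swap <- contacts$chrom_a > contacts$chrom_b
  if (any(swap)) {
    tmp_c <- contacts$chrom_a[swap]; tmp_b <- contacts$bin_a[swap]
    contacts$chrom_a[swap] <- contacts$chrom_b[swap]
    contacts$bin_a[swap] <- contacts$bin_b[swap]
    contacts$chrom_b[swap] <- tmp_c
    contacts$bin_b[swap] <- tmp_b
  }
  if (is.null(n_bins)) {
    chroms <- sort(unique(c(contacts$chrom_a, contacts$chrom_b)))
    n_bins <- vapply(chroms, function(ch) {
      max(contacts$bin_a[contacts$chrom_a == ch],
          contacts$bin_b[contacts$chrom_b == ch], 0L) + 1L
    }, numeric(1))
    names(n_bins) <- chroms
  }
  structure(contacts, class = c("contact_matrix", class(tibble())),
            resolution_bp = as.integer(resolution_bp), n_bins = n_bins)
}

#' Look up normalized contact frequencies for bin pairs
#'
#' Order-insensitive (the matrix is symmetric under pair swap); absent pairs
#' return frequency 0.
#'
#' @param contacts A `contact_matrix`.
#' @param chrom_a,bin_a,chrom_b,bin_b Vectors describing the query pairs.
#' @return Numeric vector of frequencies.
#' @export
contact_frequency <- function(contacts, chrom_a, bin_a, chrom_b, bin_b) {
  swap <- chrom_a > chrom_b
  ca <- ifelse(swap, chrom_b, chrom_a); ba <- ifelse(swap, bin_b, bin_a)
  cb <- ifelse(swap, chrom_a, chrom_b); bb <- ifelse(swap, bin_a, bin_b)
  key <- paste(ca, ba, cb, bb)
  tab_key <- paste(contacts$chrom_a, contacts$bin_a, contacts$chrom_b, contacts$bin_b)
  freq <- contacts$freq[match(key, tab_key)]
  freq[is.na(freq)] <- 0
  freq
}
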