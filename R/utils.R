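#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows n row_number across pull
#'   rename slice_min first
#' @importFrom stats cor lm pnorm qnorm pt rnorm runif rbinom rpois sd var
#'   p.adjust fisher.test ks.test wilcox.test quantile vcov coef complete.cases
#'   median prcomp setNames ave na.omit
#' @importFrom utils head
NULL

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, clamped at -Inf when the difference
# underflows (single-variant degenerate case)
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Named substreams off one root seed so regenerating one artifact does not
# perturb the others. Offsets are fixed per artifact name; result < 2^31.
substream_seed <- function(seed, name) {
  offsets <- c(
    genotypes = 11L, expression = 23L, hic = 37L, gwas = 51L,
    architecture = 67L, scan = 83L, split = 97L, mediation = 113L,
    hotspots = 131L, misc = 149L
  )
  off <- offsets[[name]]
  if (is.null(off)) abort(paste0("unknown substream '", name, "'"))
  as.integer((as.numeric(seed) * 7919 + off * 1000003) %% 2147483647)
}

# Run code under a local RNG state; seed = NULL keeps the ambient stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(as.integer(x))
}

assert_samples_aligned <- function(a, b, what) {
  if (!identical(a, b)) {
    abort(paste0("sample identifiers of ", what, " are not aligned"))
  }
}
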