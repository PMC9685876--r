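#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mediation fit
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return Tibble with one row per effect (`acme`, `ade`, `total`) holding
#'   the estimate, 95% interval and Monte-Carlo p where defined.
#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble(
    term = c("acme", "ade", "total", "prop_mediated"),
    estimate = c(x$acme, x$ade, x$total, x$prop_mediated),
    conf.low = c(x$acme_ci[1], x$ade_ci[1], x$total_ci[1], NA_real_),
    conf.high = c(x$acme_ci[2], x$ade_ci[2], x$total_ci[2], NA_real_),
    p.value = c(x$acme_p, x$ade_p, NA_real_, NA_real_)
  )
}

#' @rdname tidy.mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble(n = x$n, n_sims = x$n_sims, acme = x$acme, acme_p = x$acme_p,
         prop_mediated = x$prop_mediated)
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return Tibble with one row per hypothesis (`h0`..`h4`) and its posterior.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(
    hypothesis = c("h0", "h1", "h2", "h3", "h4"),
    description = c("no association", "trait 1 only", "trait 2 only",
                    "two distinct causal variants", "one shared causal variant"),
    posterior = as.numeric(x$pp)
  )
}

#' @rdname tidy.coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(n_variants = x$n_variants, pp4 = x$pp[["pp4"]],
         p1 = x$priors[["p1"]], p2 = x$priors[["p2"]], p12 = x$priors[["p12"]])
}
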