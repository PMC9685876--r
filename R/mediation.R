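#' Quasi-Bayesian causal mediation of a SNP effect through a cis gene
#'
#' Fits the two linear structural models by OLS -- mediator
#' `y_cis ~ g + covars` and outcome `y_trans ~ g + y_cis + covars` (no
#' exposure--mediator interaction) -- and propagates estimation uncertainty by
#' drawing `n_sims` coefficient vectors from each model's asymptotic normal.
#' Each draw's average causal mediation effect (ACME) is the product of the
#' SNP-to-mediator and mediator-to-outcome coefficients; the average direct
#' effect (ADE) is the outcome model's SNP coefficient; in this linear
#' no-interaction model the total effect is their sum.
#'
#' @param g Dosage vector.
#' @param y_cis Mediator expression vector.
#' @param y_trans Outcome expression vector.
#' @param covariates A `covariate_matrix`, plain matrix or `NULL`.
#' @param n_sims Number of Monte-Carlo coefficient draws (>= 100).
#' @param seed Seed for the draws.
#' @return A `mediation_fit`: `acme`, `ade`, `total`, `prop_mediated`,
#'   `acme_p` (two-sided Monte-Carlo p, floored at `1/(n_sims+1)`),
#'   `acme_ci` (95%), `ade_ci`, `n_sims`, `n`.
#' @export
fit_mediation <- function(g, y_cis, y_trans, covariates = NULL,
                          n_sims = 1000, seed = NULL) {
  if (n_sims < 100) abort("n_sims must be >= 100")
  n <- length(g)
  if (length(y_cis) != n || length(y_trans) != n) abort("input vectors differ in length")
  if (abs(cor(g, y_cis)) > 0.999) {
    abort("dosage and mediator are collinear (|r| > 0.999): mediation not identifiable")
  }
  X <- unclass(covariates)
  med_df <- if (is.null(X)) data.frame(y = y_cis, g = g) else
    data.frame(y = y_cis, g = g, X)
  out_df <- if (is.null(X)) data.frame(y = y_trans, g = g, m = y_cis) else
    data.frame(y = y_trans, g = g, m = y_cis, X)
  fit_m <- lm(y ~ ., data = med_df)
  fit_o <- lm(y ~ ., data = out_df)

  # quasi-Bayesian draws restricted to the slope block actually used; the
  # slope covariance is invariant to constant shifts of the inputs
  va <- vcov(fit_m)["g", "g"]
  Vo <- vcov(fit_o)[c("g", "m"), c("g", "m")]
  z <- with_seed_if(seed, list(z1 = rnorm(n_sims),
                               Z2 = matrix(rnorm(2 * n_sims), ncol = 2)))
  oc <- z$Z2 %*% chol(Vo)
  a_draw <- coef(fit_m)[["g"]] + sqrt(va) * z$z1
  c_draw <- coef(fit_o)[["g"]] + oc[, 1]
  b_draw <- coef(fit_o)[["m"]] + oc[, 2]
  acme_draw <- a_draw * b_draw
  total_draw <- acme_draw + c_draw

  mc_p <- function(d) {
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    min(max(p, 1 / (n_sims + 1)), 1)
  }
  acme <- mean(acme_draw)
  total <- mean(total_draw)
  structure(list(
    acme = acme,
    ade = mean(c_draw),
    total = total,
    prop_mediated = acme / total,
    acme_p = mc_p(acme_draw),
    ade_p = mc_p(c_draw),
    acme_ci = unname(quantile(acme_draw, c(0.025, 0.975))),
    ade_ci = unname(quantile(c_draw, c(0.025, 0.975))),
    total_ci = unname(quantile(total_draw, c(0.025, 0.975))),
    a_hat = unname(coef(fit_m)[["g"]]),
    b_hat = unname(coef(fit_o)[["m"]]),
    n_sims = n_sims, n = n
  ), class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(
    "<mediation_fit> n=%d, %d sims\n  ACME %.4f [%.4f, %.4f] p=%.4g\n  ADE  %.4f [%.4f, %.4f]\n  total %.4f, prop. mediated %.3f\n",
    x$n, x$n_sims, x$acme, x$acme_ci[1], x$acme_ci[2], x$acme_p,
    x$ade, x$ade_ci[1], x$ade_ci[2], x$total, x$prop_mediated))
  invisible(x)
}

#' Screen colocalized pairs for cis mediation
#'
#' Runs [fit_mediation()] for every colocalized (trans eSNP, cis gene, trans
#' gene) triple; pairs with `acme_p < alpha` are labelled mediated, with the
#' mediation sign taken from the ACME estimate. Per-pair failures are caught
#' and logged, not fatal.
#'
#' @param pairs Tibble from [colocalize_cis_trans()] (`variant_id`,
#'   `cis_gene`, `trans_gene`).
#' @param expr An `expression_matrix` holding both genes of every pair.
#' @param genotypes A `genotype_matrix` holding every anchor SNP.
#' @param covariates A `covariate_matrix` or `NULL`.
#' @param alpha Mediation p threshold (0.05, uncorrected, as in common
#'   practice for per-pair screens; set `adjust = "BH"` to correct).
#' @param n_sims Draws per pair.
#' @param seed Root seed (per-pair seeds are derived from it).
#' @param adjust `"none"` (default) or `"BH"` across pairs.
#' @return A `mediation_screen` tibble: pair ids, `acme`, `ade`, `total`,
#'   `prop_mediated`, `acme_p`, `sign`, `mediated`. Attributes
#'   `mediated_fraction`, `n_positive`, `n_negative` summarize the screen.
#' @export
mediation_screen <- function(pairs, expr, genotypes, covariates = NULL,
                             alpha = 0.05, n_sims = 1000, seed = 1,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(pairs) == 0) {
    out <- tibble(variant_id = character(), cis_gene = character(),
                  trans_gene = character(), acme = numeric(), ade = numeric(),
                  total = numeric(), prop_mediated = numeric(),
                  acme_p = numeric(), sign = numeric(), mediated = logical())
    return(structure(out, class = c("mediation_screen", class(tibble())),
                     mediated_fraction = NA_real_, n_positive = 0L, n_negative = 0L))
  }
  n_fail <- 0L
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    fit <- tryCatch(
      fit_mediation(
        genotypes$dosage[, pairs$variant_id[i]],
        expr$values[pairs$cis_gene[i], ],
        expr$values[pairs$trans_gene[i], ],
        covariates, n_sims = n_sims,
        seed = substream_seed(seed + i, "mediation")
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      n_fail <<- n_fail + 1L
      return(tibble(variant_id = pairs$variant_id[i],
                    cis_gene = pairs$cis_gene[i],
                    trans_gene = pairs$trans_gene[i],
                    acme = NA_real_, ade = NA_real_, total = NA_real_,
                    prop_mediated = NA_real_, acme_p = NA_real_))
    }
    tibble(variant_id = pairs$variant_id[i], cis_gene = pairs$cis_gene[i],
           trans_gene = pairs$trans_gene[i], acme = fit$acme, ade = fit$ade,
           total = fit$total, prop_mediated = fit$prop_mediated,
           acme_p = fit$acme_p)
  })
  out <- bind_rows(rows)
  if (n_fail > 0) inform(sprintf("%d mediation fit(s) failed and were skipped", n_fail))
  p_use <- if (adjust == "BH") p.adjust(out$acme_p, "BH") else out$acme_p
  out <- out |>
    mutate(sign = sign(.data$acme), mediated = !is.na(p_use) & p_use < alpha)
  structure(out, class = c("mediation_screen", class(tibble())),
            mediated_fraction = mean(out$mediated, na.rm = TRUE),
            n_positive = sum(out$mediated & out$sign > 0, na.rm = TRUE),
            n_negative = sum(out$mediated & out$sign < 0, na.rm = TRUE))
}
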