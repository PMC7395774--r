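#' Tidy a fitted PMR model
#'
#' @param x a `pmr_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and
#'   `fixed` (whether the parameter was held at zero by the variant).
#' @export
tidy.pmr_fit <- function(x, ...) {
  pr <- x$params
  tibble(
    term = c("alpha", "gamma", "sigma2_beta", "sigma2_x", "sigma2_y"),
    estimate = c(pr$alpha, pr$gamma, pr$sigma2_beta, pr$sigma2_x, pr$sigma2_y),
    fixed = c(x$variant %in% c("alpha_fixed_zero", "alpha_gamma_fixed_zero"),
              x$variant %in% c("gamma_fixed_zero", "alpha_gamma_fixed_zero"),
              FALSE, FALSE, FALSE)
  )
}

#' @rdname tidy.pmr_fit
#' @export
glance.pmr_fit <- function(x, ...) {
  tibble(variant = x$variant, logLik = x$loglik, n_iter = x$n_iter,
         converged = x$converged, p = x$p, n1 = x$n1, n2 = x$n2)
}

#' Tidy a per-gene association result
#'
#' @param x a `pmr_assoc` from [analyze_gene()].
#' @param ... unused.
#' @return A one-row tibble: `gene_id`, `alpha_hat`, `p_alpha`, `gamma_hat`,
#'   `p_gamma`, the three maximized log-likelihoods, SNP count and sample
#'   sizes, and convergence flags.
#' @export
tidy.pmr_assoc <- function(x, ...) {
  dplyr::bind_cols(
    tibble(gene_id = x$gene_id),
    tidy_assoc_row(x),
    tibble(p = x$fit_full$p, n1 = x$fit_full$n1, n2 = x$fit_full$n2,
           converged_alpha0 = x$fit_alpha0$converged,
           converged_gamma0 = x$fit_gamma0$converged)
  )
}

#' @rdname tidy.pmr_assoc
#' @export
glance.pmr_assoc <- function(x, ...) {
  tibble(p_alpha = x$test_alpha$p_value, p_gamma = x$test_gamma$p_value,
         logLik_full = x$fit_full$loglik)
}

#' Quantile-quantile plot for a vector of p-values
#'
#' Convenience wrapper building a [calibration_summary()] and plotting it.
#'
#' @param pvals numeric p-values.
#' @return A ggplot object.
#' @export
plot_qq <- function(pvals) {
  autoplot(calibration_summary(pvals))
}
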