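#' Genomic control factor of a set of p-values
#'
#' Each p-value is converted to its chi-square(1) upper-tail quantile; the
#' genomic control factor is the median of those statistics divided by the
#' chi-square(1) median, 0.4549364. Values near one indicate calibrated
#' tests, larger values inflation.
#'
#' @param pvals numeric p-values in (0, 1\].
#' @return The genomic inflation factor lambda (scalar).
#' @export
#' @examples
#' genomic_control(rep(0.5, 10))  # exactly 1
genomic_control <- function(pvals) {
  if (length(pvals) == 0) abort("empty p-value vector")
  stopifnot(all(pvals > 0), all(pvals <= 1))
  chisq <- qchisq(pvals, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Calibration summary of null p-values
#'
#' @param pvals numeric p-values from null simulations.
#' @return A list of class `pmr_calibration`: `lambda_gc`, `n_tests`, `ks_p`
#'   (Kolmogorov-Smirnov uniformity p-value), and `qq_points`, a tibble of
#'   paired expected/observed -log10 p sorted by expected quantile.
#' @export
calibration_summary <- function(pvals) {
  stopifnot(length(pvals) > 0)
  n <- length(pvals)
  obs <- sort(pvals)
  qq <- tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(obs)
  ) |> dplyr::arrange(.data$expected)
  structure(
    list(lambda_gc = genomic_control(pvals), n_tests = n,
         ks_p = suppressWarnings(ks.test(pvals, "punif")$p.value),
         qq_points = qq),
    class = "pmr_calibration"
  )
}

#' @export
print.pmr_calibration <- function(x, ...) {
  cat("<pmr_calibration> n = ", x$n_tests,
      ", lambda_GC = ", round(x$lambda_gc, 3),
      ", KS uniformity p = ", format.pval(x$ks_p), "\n", sep = "")
  invisible(x)
}

#' Quantile-quantile plot of -log10 p-values
#'
#' @param x a `pmr_calibration` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pmr_calibration
#' @export
autoplot.pmr_calibration <- function(x, ...) {
  ggplot2::ggplot(x$qq_points,
                  ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(p))),
      y = expression(Observed ~ -log[10](italic(p))),
      subtitle = sprintf("lambda[GC] = %.3f (n = %d)", x$lambda_gc, x$n_tests)
    ) +
    ggplot2::theme_minimal()
}

#' Power at a fixed empirical false discovery rate
#'
#' With known truth labels (as in simulations), finds the largest p-value
#' threshold t such that the proportion of null tests among all tests called
#' at t is at most `fdr_level`, then reports the fraction of alternative
#' tests called at t. This label-aware common-threshold construction allows
#' a fair power comparison between methods whose p-values are differently
#' calibrated. When no threshold qualifies, power is zero.
#'
#' @param pvals_null p-values from null simulations.
#' @param pvals_alt p-values from alternative simulations.
#' @param fdr_level target false discovery rate (default 0.1).
#' @return A list of class `pmr_power`: `fdr_level`, `threshold`, `power`,
#'   `n_null`, `n_alt`.
#' @export
power_at_fdr <- function(pvals_null, pvals_alt, fdr_level = 0.1) {
  stopifnot(length(pvals_null) > 0, length(pvals_alt) > 0,
            fdr_level > 0, fdr_level < 1)
  all_p <- sort(unique(c(pvals_null, pvals_alt)))
  n_null_le <- vapply(all_p, function(t) sum(pvals_null <= t), 0)
  n_tot_le <- vapply(all_p, function(t) sum(pvals_null <= t) +
                       sum(pvals_alt <= t), 0)
  ok <- n_null_le / n_tot_le <= fdr_level
  if (!any(ok)) {
    threshold <- 0
    power <- 0
  } else {
    threshold <- max(all_p[ok])
    power <- mean(pvals_alt <= threshold)
  }
  structure(list(fdr_level = fdr_level, threshold = threshold, power = power,
                 n_null = length(pvals_null), n_alt = length(pvals_alt)),
            class = "pmr_power")
}

#' @export
print.pmr_power <- function(x, ...) {
  cat("<pmr_power> power = ", round(x$power, 3), " at FDR ", x$fdr_level,
      " (threshold ", format(x$threshold, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Bias, relative bias and RMSE of parameter estimates
#'
#' @param estimates numeric vector of estimates.
#' @param truths numeric vector of matching true values (recycled if
#'   scalar).
#' @return A one-row tibble with `n`, `mean_estimate`, `mean_truth`, `bias`,
#'   `rel_bias` (NA when the mean truth is zero) and `rmse`.
#' @export
recovery_metrics <- function(estimates, truths) {
  if (length(truths) == 1) truths <- rep(truths, length(estimates))
  if (length(estimates) != length(truths))
    abort("estimates and truths have different lengths")
  err <- estimates - truths
  mt <- mean(truths)
  tibble(
    n = length(estimates),
    mean_estimate = mean(estimates),
    mean_truth = mt,
    bias = mean(err),
    rel_bias = if (mt != 0) mean(err) / mt else NA_real_,
    rmse = sqrt(mean(err^2))
  )
}
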