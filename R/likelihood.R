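#' Model parameters of the joint PMR likelihood
#'
#' @param alpha causal effect of the exposure on the outcome (trait-SD per
#'   expression-SD).
#' @param gamma common horizontal pleiotropic effect per SNP (trait-SD per
#'   standardized allele).
#' @param sigma2_beta prior variance of each SNP effect on expression.
#' @param sigma2_x expression residual variance.
#' @param sigma2_y combined outcome residual variance. The outcome residual
#'   mixes the residual of the latent expression (scaled by alpha) with the
#'   trait's own residual; the two components are not separately identifiable
#'   from two-sample data, so a single free parameter is carried.
#' @return A list of class `pmr_params`.
#' @export
pmr_params <- function(alpha = 0, gamma = 0, sigma2_beta = 1e-3,
                       sigma2_x = 1, sigma2_y = 1) {
  stopifnot(sigma2_beta >= 0, sigma2_x > 0, sigma2_y > 0)
  structure(list(alpha = alpha, gamma = gamma, sigma2_beta = sigma2_beta,
                 sigma2_x = sigma2_x, sigma2_y = sigma2_y),
            class = "pmr_params")
}

## variance floor preventing log(0); leaves MLEs unaffected at reported
## tolerance
VAR_FLOOR <- 1e-10

#' Marginal log-likelihood of the joint model
#'
#' Evaluates the log-density of the stacked phenotypes under the joint model
#' in which the polygenic SNP effects have been integrated out: the stacked
#' vector is multivariate normal with mean (0, gamma * Zy 1), covariance
#' blocks sigma2_beta Zx Zx' + sigma2_x I and
#' sigma2_beta alpha^2 Zy Zy' + sigma2_y I, and cross-block
#' sigma2_beta alpha Zx Zy'. The Woodbury and matrix-determinant identities
#' reduce everything to one p x p Cholesky factorization of the posterior
#' precision, so the cost is O(p^3) regardless of the cohort sizes and no
#' n x n matrix is ever formed.
#'
#' @param stats a [pmr_stats()] object.
#' @param params a [pmr_params()] object.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(stats, params) {
  stopifnot(inherits(stats, "pmr_stats"), inherits(params, "pmr_params"))
  ll <- loglik_core(stats, params$alpha, params$gamma,
                    max(params$sigma2_beta, VAR_FLOOR),
                    max(params$sigma2_x, VAR_FLOOR),
                    max(params$sigma2_y, VAR_FLOOR))$ll
  if (!is.finite(ll))
    abort(paste0("non-finite log-likelihood at sigma2_beta=",
                 params$sigma2_beta, ", sigma2_x=", params$sigma2_x,
                 ", sigma2_y=", params$sigma2_y))
  ll
}

## Shared computational core: posterior precision P, its Cholesky factor,
## posterior mean m of the latent SNP effects, and the marginal loglik.
## P = Cxx/sx + (a^2/sy) Cyy + I/sb ;  v = cx/sx + (a/sy)(cy - g Cyy 1)
## log|Sigma| = n1 log sx + n2 log sy + p log sb + log|P|
## quad = sxx/sx + |y - g Zy 1|^2/sy - v' P^{-1} v
loglik_core <- function(stats, a, g, sb, sx, sy) {
  p <- stats$p
  Cy1 <- drop(stats$Cyy %*% rep(1, p))
  s1 <- sum(Cy1)
  sy1 <- sum(stats$cy)
  P <- stats$Cxx / sx + (a^2 / sy) * stats$Cyy
  diag(P) <- diag(P) + 1 / sb
  R <- chol(P)
  v <- stats$cx / sx + (a / sy) * (stats$cy - g * Cy1)
  m <- backsolve(R, backsolve(R, v, transpose = TRUE))
  rss_y <- stats$syy - 2 * g * sy1 + g^2 * s1
  ll <- -0.5 * ((stats$n1 + stats$n2) * log(2 * pi) +
                  stats$n1 * log(sx) + stats$n2 * log(sy) + p * log(sb) +
                  2 * sum(log(diag(R))) +
                  stats$sxx / sx + rss_y / sy - sum(v * m))
  list(ll = ll, R = R, m = m, v = v, Cy1 = Cy1, s1 = s1, sy1 = sy1)
}

#' Posterior distribution of the latent SNP effects
#'
#' Closed-form conditional of the polygenic effects given both studies:
#' precision Cxx/sigma2_x + alpha^2 Cyy/sigma2_y + I/sigma2_beta, with mean
#' precision^-1 (cx/sigma2_x + alpha (cy - gamma Cyy 1)/sigma2_y).
#'
#' @inheritParams marginal_loglik
#' @return A list with elements `mean` (p-vector) and `cov` (p x p matrix).
#' @export
beta_posterior <- function(stats, params) {
  stopifnot(inherits(stats, "pmr_stats"), inherits(params, "pmr_params"))
  core <- loglik_core(stats, params$alpha, params$gamma,
                      max(params$sigma2_beta, VAR_FLOOR),
                      max(params$sigma2_x, VAR_FLOOR),
                      max(params$sigma2_y, VAR_FLOOR))
  list(mean = core$m, cov = chol2inv(core$R))
}
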