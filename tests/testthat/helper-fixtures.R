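## Small in-code fixtures shared across test files.

## unstructured tiny two-study dataset with explicit genotype matrices,
## for oracle comparisons against dense multivariate-normal computations
tiny_dataset <- function(n1 = 20, n2 = 30, p = 5, seed = 1,
                         alpha = 0, gamma = 0, sb = 0.05) {
  withr::with_seed(seed, {
    Zx <- matrix(rnorm(n1 * p), n1, p)
    Zy <- matrix(rnorm(n2 * p), n2, p)
    beta <- rnorm(p, 0, sqrt(sb))
    x <- drop(Zx %*% beta) + rnorm(n1)
    y <- alpha * drop(Zy %*% beta) + gamma * rowSums(Zy) + rnorm(n2)
    list(Zx = Zx, Zy = Zy, x = x, y = y, beta = beta)
  })
}

stats_from_matrices <- function(d) {
  pmr_stats(crossprod(d$Zx), drop(crossprod(d$Zx, d$x)), sum(d$x^2),
            nrow(d$Zx),
            crossprod(d$Zy), drop(crossprod(d$Zy, d$y)), sum(d$y^2),
            nrow(d$Zy))
}

random_params <- function(seed) {
  withr::with_seed(seed, pmr_params(
    alpha = rnorm(1), gamma = rnorm(1, 0, 0.2),
    sigma2_beta = runif(1, 0.01, 0.5),
    sigma2_x = runif(1, 0.3, 2), sigma2_y = runif(1, 0.3, 2)
  ))
}

## dense multivariate-normal log-density oracle built from explicit
## genotype matrices (never used by the implementation itself)
dense_loglik_oracle <- function(d, params) {
  n1 <- nrow(d$Zx); n2 <- nrow(d$Zy)
  A <- rbind(d$Zx, params$alpha * d$Zy)
  Sig <- params$sigma2_beta * tcrossprod(A) +
    diag(c(rep(params$sigma2_x, n1), rep(params$sigma2_y, n2)))
  mu <- c(rep(0, n1), params$gamma * rowSums(d$Zy))
  u <- c(d$x, d$y) - mu
  -0.5 * ((n1 + n2) * log(2 * pi) +
            as.numeric(determinant(Sig)$modulus) + sum(u * solve(Sig, u)))
}

## small scenario used by several test files: modest sizes, fast fits
small_scenario <- function(..., p = 60, n1 = 150, n2 = 400, n_reps = 50,
                           seed = 7L) {
  simulation_scenario(n1 = n1, n2 = n2, p = p, n_reps = n_reps, seed = seed,
                      ld = ld_spec(p, block_size = 10), ...)
}
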