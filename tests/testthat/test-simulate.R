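test_that("simulated genotype panels are reproducible and standardized", {
  ld <- ld_spec(30, block_size = 10)
  p1 <- simulate_genotypes(200, ld, seed = 5)
  p2 <- simulate_genotypes(200, ld, seed = 5)
  expect_identical(p1$Z, p2$Z)
  expect_no_error(validate_panel(p1))
  expect_equal(p1$p, 30)
})

test_that("rho = 0 gives near-independent SNPs at large n", {
  ld <- ld_spec(20, block_size = 5, within_block_rho = 0)
  panel <- simulate_genotypes(2000, ld, seed = 6)
  R <- cor(panel$Z)
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)
})

test_that("within-block allelic correlation matches the thresholded-Gaussian target", {
  ## Monte-Carlo oracle: simulate two latent-Gaussian haplotype coordinates
  ## at rho = 0.7 and maf 0.3, threshold, and compare the implied genotype
  ## correlation with the panel's empirical one
  rho <- 0.7; maf <- 0.3
  withr::with_seed(77, {
    m <- 4e5
    g <- rnorm(m)
    l1 <- sqrt(rho) * g + sqrt(1 - rho) * rnorm(m)
    l2 <- sqrt(rho) * g + sqrt(1 - rho) * rnorm(m)
    target <- cor(l1 < qnorm(maf), l2 < qnorm(maf))
  })
  ld <- ld_spec(10, block_size = 10, within_block_rho = rho,
                maf_range = c(0.3, 0.3), neg_loading_frac = 0)
  panel <- simulate_genotypes(5000, ld, seed = 8)
  R <- cor(panel$Z)
  off <- R[upper.tri(R)]
  expect_lt(abs(mean(off) - target), 0.05)
  expect_lt(sd(off), 0.05)
})

test_that("coding flips change correlation signs with exact symmetry", {
  ld0 <- ld_spec(10, block_size = 10, within_block_rho = 0.7,
                 neg_loading_frac = 0)
  ld <- realize_ld(ld0, seed = 41)
  panel0 <- simulate_genotypes(1500, ld, seed = 42)
  ld$coding_sign <- rep(c(1L, -1L), 5)
  panel <- simulate_genotypes(1500, ld, seed = 42)
  same <- outer(ld$coding_sign, ld$coding_sign)
  ## identical draws up to column sign: R flips are exact
  expect_equal(cor(panel$Z), cor(panel0$Z) * same, tolerance = 1e-12)
  R <- cor(panel$Z)
  expect_gt(mean(R[upper.tri(R)][same[upper.tri(same)] > 0]), 0.2)
  expect_lt(mean(R[upper.tri(R)][same[upper.tri(same)] < 0]), -0.2)
})

test_that("alpha_from_pve implements the variance-budget ratio", {
  expect_equal(alpha_from_pve(0, 0.1), 0)
  expect_equal(alpha_from_pve(0.006, 0.1), sqrt(0.06))
  expect_equal(alpha_from_pve(0.05, 0.05), 1)
  expect_error(alpha_from_pve(0.1, 0), "positive")
})

test_that("simulate_beta hits the variance budget across sparsity levels", {
  ## dense: each effect ~ N(0, pve/p)
  withr::with_seed(9, {
    draws <- replicate(4000, simulate_beta(50, 0.1))
  })
  expect_equal(var(as.vector(draws)), 0.1 / 50, tolerance = 0.05)
  b1 <- simulate_beta(50, 0.1, n_causal = 1, seed = 10)
  expect_equal(sum(b1 != 0), 1)
  b1pc <- simulate_beta(200, 0.1, prop_causal = 0.1, seed = 11)
  expect_equal(sum(b1pc != 0), 20)
  expect_error(simulate_beta(50, 0.1, prop_causal = 0), "zero causal")
  ## correlated draw with identity covariance reduces to the independent case
  withr::with_seed(12, {
    dI <- replicate(2000, simulate_beta(20, 0.1, Sigma = diag(20)))
  })
  expect_equal(var(as.vector(dI)), 0.1 / 20, tolerance = 0.08)
})

test_that("expression and trait generators respect their variance budgets", {
  ld <- ld_spec(40, block_size = 10)
  panel <- simulate_genotypes(400, ld, seed = 13)
  beta <- simulate_beta(40, 0.3, seed = 14)
  ## noiseless limit: expression equals the genetic score
  x1 <- simulate_expression(panel, beta, pve_zx = 1 - 1e-12, seed = 15)
  expect_equal(x1, drop(panel$Z %*% beta), tolerance = 1e-5)
  ## pure noise when beta = 0
  x0 <- simulate_expression(panel, numeric(40), pve_zx = 0.3, seed = 16)
  expect_equal(var(x0), 0.7, tolerance = 0.15)
  ## trait construction is exact given the noise
  gvec <- rep(2e-3, 40)
  y <- simulate_trait(panel, numeric(40), 0, gvec, 0, seed = 17)
  eps <- y - drop(panel$Z %*% gvec)
  expect_equal(var(eps), 1, tolerance = 0.2)

  ## mean realized expression heritability over replicates tracks pve_zx
  r2 <- replicate(60, {
    b <- simulate_beta(40, 0.1)
    xx <- simulate_expression(panel, b, 0.1)
    g <- drop(panel$Z %*% b)
    var(g) / var(xx)
  })
  expect_equal(mean(r2), 0.1, tolerance = 0.2)  # within 20% relative
})

test_that("simulate_gamma obeys counts, magnitudes and sign ratios", {
  g <- simulate_gamma(556, 5e-4, 1, 0, seed = 18)
  expect_true(all(g == 5e-4))
  g0 <- simulate_gamma(20, 0)
  expect_equal(g0, numeric(20))
  g5 <- simulate_gamma(10, 1e-3, prop_nonzero = 0.5, prop_negative = 0.5,
                       seed = 19)
  expect_equal(sum(g5 != 0), 5)
  expect_equal(sum(g5 < 0), 2)  # positive side receives the remainder
  expect_equal(sum(g5 > 0), 3)
  expect_true(all(abs(g5[g5 != 0]) == 1e-3))
  g37 <- simulate_gamma(100, 1e-3, prop_nonzero = 1, prop_negative = 0.3,
                        seed = 20)
  expect_equal(sum(g37 < 0), 30)
})

test_that("run_scenario is reproducible and returns one row per replicate", {
  sc <- small_scenario(n_reps = 3)
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3)
  expect_true(all(r1$p_alpha >= 0 & r1$p_alpha <= 1))
  sc1 <- small_scenario(n_reps = 1)
  expect_equal(nrow(run_scenario(sc1)), 1)
})

test_that("cross-gene mode regenerates genotypes between replicates", {
  sc <- small_scenario(n_reps = 2, cross_gene = TRUE)
  r <- run_scenario(sc)
  expect_equal(nrow(r), 2)
  expect_false(isTRUE(all.equal(r$loglik_full[1], r$loglik_full[2])))
})

test_that("scenario files round-trip through the key = value format", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "n1 = 100", "n2 = 200", "p = 25",
               "pve_zx = 0.05", "gamma_magnitude = 5e-4",
               "prop_negative = 0.5", "n_reps = 7", "seed = 3"), path)
  sc <- read_scenario(path)
  expect_equal(sc$n1, 100L)
  expect_equal(sc$p, 25L)
  expect_equal(sc$gamma_magnitude, 5e-4)
  expect_equal(sc$prop_negative, 0.5)
  expect_equal(sc$n_reps, 7L)
})
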