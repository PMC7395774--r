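## build matched individual-level data and the summaries a study would
## publish from it
summary_fixture <- function(seed = 1, p = 30, n1 = 300, n2 = 800,
                            pve_zx = 0.3, alpha = 0.3) {
  ld <- ld_spec(p, block_size = 10)
  ldr <- realize_ld(ld, seed = seed)
  px <- simulate_genotypes(n1, ldr, seed = seed + 1)
  py <- simulate_genotypes(n2, ldr, seed = seed + 2)
  beta <- simulate_beta(p, pve_zx, seed = seed + 3)
  x <- simulate_expression(px, beta, pve_zx, seed = seed + 4)
  y <- simulate_trait(py, beta, alpha, numeric(p), 0.05, seed = seed + 5)
  dat <- individual_data(px, x, py, y)
  list(dat = dat,
       eqtl = summarize_panel(px, x), gwas = summarize_panel(py, y),
       ld_x = ld_from_panel(px), ld_y = ld_from_panel(py))
}

test_that("z to standardized-beta conversion is exact arithmetic", {
  expect_equal(std_beta(3, 101), 3 / sqrt(108), tolerance = 1e-12)
  expect_equal(std_beta(0, 50), 0)
})

test_that("summary statistics reconstruct the sufficient statistics", {
  fx <- summary_fixture(seed = 60)
  st_ind <- compute_sufficient_stats(fx$dat)
  st_sum <- stats_from_summary(fx$eqtl, fx$gwas, fx$ld_x, fx$ld_y)
  n1 <- fx$dat$panel_x$n
  ## recovery up to O(1/n) from the z-to-beta bridge
  expect_lt(max(abs(st_sum$Cxx - st_ind$Cxx)), 0.02 * n1)
  expect_lt(max(abs(st_sum$cx - st_ind$cx)), 0.02 * n1)
  expect_lt(max(abs(st_sum$cy - st_ind$cy)), 0.02 * fx$dat$panel_y$n)
})

test_that("summary-mode p-values agree with the individual-level mode", {
  fx <- summary_fixture(seed = 61)
  a_ind <- tidy(analyze_gene(compute_sufficient_stats(fx$dat)))
  a_sum <- tidy(analyze_gene(stats_from_summary(fx$eqtl, fx$gwas,
                                                fx$ld_x, fx$ld_y)))
  expect_lt(abs(log10(a_ind$p_alpha) - log10(a_sum$p_alpha)), 0.1)
  expect_lt(abs(log10(a_ind$p_gamma) - log10(a_sum$p_gamma)), 0.1)
})

test_that("all-zero z-scores give zero cross-products and null estimates", {
  p <- 10
  ms <- marginal_summary(paste0("s", 1:p), rep("A", p), rep("G", p),
                         rep(0, p), rep(0.1, p), 500)
  ld <- ld_matrix(diag(p), paste0("s", 1:p))
  st <- stats_from_summary(ms, ms, ld, ld)
  expect_equal(st$cx, rep(0, p))
  expect_equal(st$cy, rep(0, p))
  fit <- fit_em(st, "full")
  expect_lt(abs(fit$params$alpha), 1e-4)
  expect_lt(abs(fit$params$gamma), 1e-6)
})

test_that("harmonize aligns alleles, flips signs and drops palindromes", {
  eqtl <- marginal_summary(c("s1", "s2", "s3", "s4"),
                           c("A", "A", "C", "A"), c("G", "T", "T", "C"),
                           c(0.1, 0.2, 0.3, 0.4), rep(0.05, 4), 400)
  gwas <- marginal_summary(c("s2", "s1", "s3", "s5"),
                           c("A", "G", "T", "A"), c("T", "A", "C", "G"),
                           c(0.15, 0.25, 0.35, 0.45), rep(0.05, 4), 900)
  ld <- ld_matrix(diag(4), c("s1", "s2", "s3", "s4"))
  expect_message(h <- harmonize(eqtl, gwas, ld), "dropped")
  ## s2 is A/T palindromic -> dropped; s4/s5 unshared -> gone
  expect_equal(h$eqtl$snp_ids, c("s1", "s3"))
  expect_true("s2" %in% h$dropped$snp)
  ## s1: gwas effect allele G vs eqtl A -> sign flip
  expect_equal(h$gwas$beta[1], -0.25)
  ## s3: alleles swapped C/T vs T/C -> sign flip
  expect_equal(h$gwas$beta[2], -0.35)
  disjoint <- marginal_summary("zz", "A", "G", 0.1, 0.1, 100)
  expect_error(harmonize(eqtl, disjoint, ld), "no shared SNPs")
})

test_that("LD regularization fixes identity, floors eigenvalues, shrinks", {
  I5 <- diag(5)
  expect_equal(regularize_ld(I5, "eigen_floor")$R, I5)
  expect_equal(regularize_ld(I5, "shrink_to_identity", 0.3)$R, I5)
  ## rank-deficient matrix from n_ref < p gets floored
  withr::with_seed(62, Z <- matrix(rnorm(4 * 10), 4, 10))
  R <- cor(rbind(Z, Z))
  reg <- regularize_ld(R, "eigen_floor", 1e-4)
  ev <- eigen(reg$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(reg$R), rep(1, 10))
  ## full shrinkage returns exactly the identity
  expect_equal(regularize_ld(R, "shrink_to_identity", 1)$R, diag(10))
  expect_error(regularize_ld(matrix(1:4, 2), "eigen_floor"),
               "not symmetric")
})

test_that("summary TSV and LD files round-trip through their readers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    snp = c("s1", "s2"), effect_allele = c("A", "C"),
    other_allele = c("G", "T"), beta = c(0.1, -0.2),
    se = c(0.05, 0.04), n = 500), path)
  ms <- read_marginal_summary(path)
  expect_equal(ms$z, c(0.1 / 0.05, -0.2 / 0.04))
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(snp = "s1", beta = 0.1), bad)
  expect_error(read_marginal_summary(bad), "missing required columns")

  ldp <- withr::local_tempfile(fileext = ".txt")
  R <- matrix(c(1, 0.4, 0.4, 1), 2)
  write.table(R, ldp, row.names = FALSE, col.names = FALSE)
  ld <- read_ld_matrix(ldp, c("s1", "s2"))
  expect_equal(ld$R, R)
})

test_that("reference-panel mismatch degrades p-value agreement monotonically", {
  ## 30 simulated genes; LD for the GWAS side taken from (i) the GWAS
  ## cohort itself, (ii) a 10% subsample, (iii) an unrelated panel with a
  ## different LD structure; agreement with the individual-level run should
  ## degrade in that order
  n_genes <- 30
  cors <- matrix(NA_real_, n_genes, 3)
  for (g in seq_len(n_genes)) {
    fx <- summary_fixture(seed = 700 + 13 * g, p = 25, n1 = 250, n2 = 600,
                          alpha = if (g %% 2) 0.35 else 0)
    py <- fx$dat$panel_y
    sub <- withr::with_seed(g, sample.int(py$n, round(0.1 * py$n)))
    panel_sub <- py
    panel_sub$Z <- py$Z[sub, , drop = FALSE]
    panel_sub$Z <- scale(panel_sub$Z)
    panel_sub$n <- length(sub)
    mism <- simulate_genotypes(
      600, ld_spec(25, block_size = 5, within_block_rho = 0.2,
                   neg_loading_frac = 0.5), seed = 9000 + g)
    lds <- list(fx$ld_y,
                regularize_ld(ld_from_panel(panel_sub)$R,
                              snp_ids = py$snp_ids),
                ld_from_panel(mism))
    p_ind <- tidy(analyze_gene(compute_sufficient_stats(fx$dat)))$p_alpha
    for (k in 1:3) {
      st <- stats_from_summary(fx$eqtl, fx$gwas, fx$ld_x, lds[[k]])
      p_sum <- tidy(analyze_gene(st))$p_alpha
      cors[g, k] <- abs(log10(pmax(p_sum, 1e-12)) -
                          log10(pmax(p_ind, 1e-12)))
    }
  }
  err <- colMeans(cors)
  expect_lt(err[1], err[2])
  expect_lt(err[2], err[3])
})
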