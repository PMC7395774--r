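#' Marginal summary statistics for one study
#'
#' Per-SNP marginal effect estimates and standard errors from a simple
#' regression of the phenotype on each SNP in turn, as distributed by eQTL
#' and GWAS consortia.
#'
#' @param snp_ids SNP identifiers.
#' @param effect_allele,other_allele allele labels; `beta` is per copy of
#'   `effect_allele`.
#' @param beta marginal effect estimates.
#' @param se standard errors (> 0).
#' @param n study sample size.
#' @return A list of class `pmr_summary`, with `z = beta / se` attached.
#' @export
marginal_summary <- function(snp_ids, effect_allele, other_allele, beta, se,
                             n) {
  p <- length(snp_ids)
  stopifnot(length(beta) == p, length(se) == p, length(effect_allele) == p,
            length(other_allele) == p, all(se > 0), n > 2)
  structure(list(snp_ids = as.character(snp_ids),
                 effect_allele = toupper(effect_allele),
                 other_allele = toupper(other_allele),
                 beta = as.numeric(beta), se = as.numeric(se),
                 n = n, z = as.numeric(beta) / as.numeric(se), p = p),
            class = "pmr_summary")
}

#' Read marginal summary statistics from a TSV file
#'
#' Requires header columns `snp`, `effect_allele`, `other_allele`, `beta`,
#' `se`, `n`.
#'
#' @param path file path.
#' @return A [marginal_summary()] object.
#' @export
read_marginal_summary <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "beta", "se", "n")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  marginal_summary(d$snp, d$effect_allele, d$other_allele, d$beta, d$se,
                   d$n[1])
}

#' SNP-by-SNP correlation matrix from a reference panel
#'
#' @param R p x p correlation matrix (unit diagonal, symmetric).
#' @param snp_ids SNP identifiers matching the rows/columns.
#' @param n_ref reference panel size.
#' @return A list of class `pmr_ld`.
#' @export
ld_matrix <- function(R, snp_ids = NULL, n_ref = NA_integer_) {
  R <- as.matrix(R)
  p <- nrow(R)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  stopifnot(ncol(R) == p, length(snp_ids) == p)
  if (max(abs(R - t(R))) > 1e-8) abort("LD matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-6) abort("LD matrix must have unit diagonal")
  if (max(abs(R)) > 1 + 1e-8) abort("LD entries must lie in [-1, 1]")
  structure(list(R = (R + t(R)) / 2, snp_ids = as.character(snp_ids),
                 n_ref = n_ref, p = p),
            class = "pmr_ld")
}

#' Compute an LD matrix from a genotype panel
#'
#' @param panel a `pmr_panel` (e.g. a reference cohort).
#' @return A [ld_matrix()] with `n_ref = panel$n`.
#' @export
ld_from_panel <- function(panel) {
  stopifnot(inherits(panel, "pmr_panel"))
  R <- crossprod(panel$Z) / (panel$n - 1)
  diag(R) <- 1
  ld_matrix(R, panel$snp_ids, panel$n)
}

#' Read a square whitespace-delimited LD matrix from disk
#'
#' @param path file path.
#' @param snp_ids optional identifiers.
#' @param n_ref optional reference panel size.
#' @return A [ld_matrix()].
#' @export
read_ld_matrix <- function(path, snp_ids = NULL, n_ref = NA_integer_) {
  R <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(R) <- NULL
  ld_matrix(R, snp_ids, n_ref)
}

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize eQTL and GWAS summaries onto shared, allele-aligned SNPs
#'
#' Restricts both studies and the LD matrix to the SNPs they share, in the
#' eQTL study's order; flips the sign of GWAS effects where the two studies
#' report opposite effect alleles; drops strand-ambiguous (A/T, C/G) SNPs
#' and SNPs whose allele pairs are incompatible, with a report.
#'
#' @param eqtl,gwas [marginal_summary()] objects.
#' @param ld a [ld_matrix()] covering at least the shared SNPs.
#' @return A list with elements `eqtl`, `gwas`, `ld`, and `dropped`, a
#'   tibble of removed SNPs and reasons.
#' @export
harmonize <- function(eqtl, gwas, ld) {
  stopifnot(inherits(eqtl, "pmr_summary"), inherits(gwas, "pmr_summary"),
            inherits(ld, "pmr_ld"))
  shared <- intersect(eqtl$snp_ids, intersect(gwas$snp_ids, ld$snp_ids))
  if (length(shared) == 0) abort("no shared SNPs between the two studies")
  shared <- eqtl$snp_ids[eqtl$snp_ids %in% shared]  # canonical (eQTL) order

  ie <- match(shared, eqtl$snp_ids)
  ig <- match(shared, gwas$snp_ids)

  pair_e <- paste0(eqtl$effect_allele[ie], "/", eqtl$other_allele[ie])
  ambiguous <- pair_e %in% PALINDROMIC
  same <- eqtl$effect_allele[ie] == gwas$effect_allele[ig] &
    eqtl$other_allele[ie] == gwas$other_allele[ig]
  swapped <- eqtl$effect_allele[ie] == gwas$other_allele[ig] &
    eqtl$other_allele[ie] == gwas$effect_allele[ig]
  incompatible <- !(same | swapped)

  keep <- !ambiguous & !incompatible
  dropped <- tibble(
    snp = shared[!keep],
    reason = dplyr::case_when(
      ambiguous[!keep] ~ "strand-ambiguous",
      TRUE ~ "incompatible alleles"
    )
  )
  if (nrow(dropped) > 0)
    inform(paste0(nrow(dropped), " SNP(s) dropped during harmonization (",
                  sum(ambiguous), " strand-ambiguous, ",
                  sum(incompatible), " incompatible)"))
  if (!any(keep)) abort("no SNPs remain after harmonization")

  ie <- ie[keep]; ig <- ig[keep]
  flip <- swapped[keep]
  gwas_beta <- gwas$beta[ig]
  gwas_beta[flip] <- -gwas_beta[flip]

  il <- match(shared[keep], ld$snp_ids)
  list(
    eqtl = marginal_summary(eqtl$snp_ids[ie], eqtl$effect_allele[ie],
                            eqtl$other_allele[ie], eqtl$beta[ie],
                            eqtl$se[ie], eqtl$n),
    gwas = marginal_summary(eqtl$snp_ids[ie], eqtl$effect_allele[ie],
                            eqtl$other_allele[ie], gwas_beta,
                            gwas$se[ig], gwas$n),
    ld = ld_matrix(ld$R[il, il, drop = FALSE], ld$snp_ids[il], ld$n_ref),
    dropped = dropped
  )
}

#' Regularize a raw LD correlation matrix
#'
#' `eigen_floor` clips eigenvalues below `level * lambda_max` (default
#' 1e-6 * lambda_max) and rescales back to a unit diagonal; it distorts a
#' full-rank matrix minimally while guaranteeing that downstream precision
#' matrices are invertible. `shrink_to_identity` returns
#' (1 - level) R + level I.
#'
#' @param R raw square symmetric correlation matrix.
#' @param method `"eigen_floor"` or `"shrink_to_identity"`.
#' @param level floor (relative to the largest eigenvalue) or shrinkage
#'   weight.
#' @param snp_ids,n_ref metadata forwarded to [ld_matrix()].
#' @return A [ld_matrix()].
#' @export
regularize_ld <- function(R, method = c("eigen_floor", "shrink_to_identity"),
                          level = NULL, snp_ids = NULL, n_ref = NA_integer_) {
  method <- match.arg(method)
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) abort("LD matrix is not symmetric")
  if (method == "eigen_floor") {
    if (is.null(level)) level <- 1e-6
    e <- eigen(R, symmetric = TRUE)
    floor_val <- level * max(e$values)
    vals <- pmax(e$values, floor_val)
    Rr <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(Rr))
    Rr <- Rr / tcrossprod(d)
    diag(Rr) <- 1
  } else {
    if (is.null(level)) level <- 0.1
    stopifnot(level >= 0, level <= 1)
    Rr <- (1 - level) * R
    diag(Rr) <- (1 - level) * diag(R) + level
  }
  ld_matrix(Rr, snp_ids, n_ref)
}

#' Reconstruct sufficient statistics from summary statistics plus LD
#'
#' With standardized genotypes and phenotypes, the cross-products that drive
#' the likelihood are recovered as Cxx = n1 Rx, cx = n1 b_std_x, sxx = n1
#' (and analogously for the GWAS), where the marginal estimate of SNP j is
#' moved onto the standardized scale through its z-score:
#' b_std = z / sqrt(n - 2 + z^2). This conversion removes any dependence on
#' the unknown phenotype and genotype scales of the original studies.
#'
#' @param eqtl,gwas harmonized [marginal_summary()] objects.
#' @param ld_x LD matrix for the expression cohort.
#' @param ld_y LD matrix for the GWAS cohort (e.g. from a reference panel).
#' @return A [pmr_stats()] object.
#' @export
stats_from_summary <- function(eqtl, gwas, ld_x, ld_y) {
  stopifnot(inherits(eqtl, "pmr_summary"), inherits(gwas, "pmr_summary"),
            inherits(ld_x, "pmr_ld"), inherits(ld_y, "pmr_ld"))
  p <- eqtl$p
  if (gwas$p != p || ld_x$p != p || ld_y$p != p)
    abort("SNP count mismatch between summaries and LD matrices")
  if (!identical(eqtl$snp_ids, gwas$snp_ids))
    abort("summaries are not harmonized (snp_ids differ)")
  bx <- std_beta(eqtl$z, eqtl$n)
  by <- std_beta(gwas$z, gwas$n)
  pmr_stats(
    Cxx = eqtl$n * ld_x$R, cx = eqtl$n * bx, sxx = eqtl$n, n1 = eqtl$n,
    Cyy = gwas$n * ld_y$R, cy = gwas$n * by, syy = gwas$n, n2 = gwas$n,
    snp_ids = eqtl$snp_ids
  )
}

#' Standardized-scale marginal effect from a z-score
#'
#' @param z marginal z-scores.
#' @param n study sample size.
#' @return Effects on the standardized-phenotype, standardized-genotype
#'   scale: z / sqrt(n - 2 + z^2).
#' @export
std_beta <- function(z, n) z / sqrt(n - 2 + z^2)

#' Marginal summaries computed from individual-level data
#'
#' Runs the per-SNP simple regressions that a study would publish; useful
#' for validating the summary-statistics mode against the individual-level
#' mode on simulated data.
#'
#' @param panel a `pmr_panel`.
#' @param y centered, scaled phenotype vector.
#' @return A [marginal_summary()].
#' @export
summarize_panel <- function(panel, y) {
  stopifnot(inherits(panel, "pmr_panel"), length(y) == panel$n)
  y <- drop(scale(y))
  n <- panel$n
  czy <- drop(crossprod(panel$Z, y))
  css <- colSums(panel$Z^2)
  b <- czy / css
  rss <- sum(y^2) - b * czy
  se <- sqrt(rss / (n - 2) / css)
  marginal_summary(panel$snp_ids, panel$effect_allele, panel$other_allele,
                   b, se, n)
}
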