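#' Standardized genotype panel
#'
#' A `pmr_panel` holds a column-standardized genotype matrix together with its
#' SNP metadata. Columns are mean-centered and scaled to unit sample variance;
#' the counted allele is oriented to be the minor allele (optionally the minor
#' allele of a designated reference study, as is conventional when the GWAS
#' cohort defines allele orientation).
#'
#' @param Z numeric matrix, n individuals x p SNPs, standardized columns.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param effect_allele,other_allele per-SNP allele labels; `effect_allele`
#'   is the counted (minor) allele.
#' @param maf per-SNP minor allele frequency, in (0, 0.5].
#'
#' @return An object of class `pmr_panel` with elements `Z`, `snp_ids`,
#'   `effect_allele`, `other_allele`, `maf`, `n`, `p`.
#' @keywords internal
new_pmr_panel <- function(Z, snp_ids, effect_allele, other_allele, maf) {
  structure(
    list(
      Z = Z, snp_ids = snp_ids,
      effect_allele = effect_allele, other_allele = other_allele,
      maf = maf, n = nrow(Z), p = ncol(Z)
    ),
    class = "pmr_panel"
  )
}

#' @export
print.pmr_panel <- function(x, ...) {
  cat("<pmr_panel> ", x$n, " individuals x ", x$p, " SNPs\n", sep = "")
  invisible(x)
}

#' Validate the invariants of a standardized panel
#'
#' Checks column centering, unit variance, absence of missing values,
#' uniqueness of SNP ids and strictly positive minor allele frequencies.
#'
#' @param panel a `pmr_panel`.
#' @return `panel`, invisibly; errors if an invariant is violated.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "pmr_panel"))
  Z <- panel$Z
  if (anyNA(Z)) abort("panel contains missing genotypes after standardization")
  cm <- colMeans(Z)
  if (any(abs(cm) >= 1e-8)) abort("panel columns are not mean-centered")
  cv <- apply(Z, 2, var)
  if (any(abs(cv - 1) >= 1e-6)) abort("panel columns do not have unit variance")
  if (anyDuplicated(panel$snp_ids)) abort("duplicated SNP identifiers in panel")
  if (any(panel$maf <= 0)) abort("monomorphic SNP retained in panel (maf == 0)")
  invisible(panel)
}

#' Standardize a raw genotype matrix into an analysis-ready panel
#'
#' Takes allele counts (0/1/2, `NA` for missing), resolves missingness by
#' per-column mean imputation, orients each SNP so that the counted allele is
#' the minor allele (by default in this matrix; a reference allele frequency,
#' e.g. from the GWAS cohort, can override the orientation), drops
#' monomorphic columns, and centers/scales every column to zero mean and unit
#' sample variance.
#'
#' @param raw integer/numeric matrix of allele counts (n x p), `NA` allowed.
#' @param snp_ids character SNP identifiers (length p). Defaults to column
#'   names or `snp1..snpP`.
#' @param effect_allele,other_allele optional allele labels for the counted
#'   and the non-counted allele; swapped for columns whose orientation is
#'   flipped.
#' @param ref_freq optional numeric vector of counted-allele frequencies in a
#'   reference study; when supplied, orientation (which allele is counted)
#'   follows the reference study rather than this matrix.
#' @return A [new_pmr_panel()] object.
#' @export
#'
#' @examples
#' raw <- cbind(a = c(0, 1, 2, 1), b = c(2, 2, 2, 2))
#' p <- standardize_panel(raw)   # monomorphic column 'b' is dropped
#' p$p
standardize_panel <- function(raw, snp_ids = NULL,
                              effect_allele = NULL, other_allele = NULL,
                              ref_freq = NULL) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) abort("at least two individuals are required")
  p0 <- ncol(raw)
  if (is.null(snp_ids)) {
    snp_ids <- colnames(raw)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p0))
  }
  if (is.null(effect_allele)) effect_allele <- rep(NA_character_, p0)
  if (is.null(other_allele)) other_allele <- rep(NA_character_, p0)
  stopifnot(length(snp_ids) == p0)

  n_obs <- colSums(!is.na(raw))
  all_missing <- n_obs == 0L
  if (any(all_missing)) {
    warn(paste0(sum(all_missing), " all-missing SNP column(s) dropped"))
  }

  ## mean-impute missing entries per column before centering
  mu <- colMeans(raw, na.rm = TRUE)
  mu[all_missing] <- NA_real_
  na_idx <- which(is.na(raw), arr.ind = TRUE)
  if (nrow(na_idx) > 0) raw[na_idx] <- mu[na_idx[, 2]]

  ## orient the counted allele to be the minor allele (in `raw` or in the
  ## reference study when given)
  freq <- mu / 2
  orient_freq <- if (is.null(ref_freq)) freq else ref_freq
  flip <- !is.na(orient_freq) & orient_freq > 0.5
  if (any(flip)) {
    raw[, flip] <- 2 - raw[, flip]
    tmp <- effect_allele[flip]
    effect_allele[flip] <- other_allele[flip]
    other_allele[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }

  sds <- apply(raw, 2, sd)
  mono <- all_missing | is.na(sds) | sds == 0 | freq == 0 | freq == 1
  n_mono <- sum(mono & !all_missing)
  if (n_mono > 0) {
    inform(paste0(n_mono, " monomorphic SNP column(s) dropped"))
  }
  keep <- which(!mono)
  if (length(keep) == 0L) abort("no polymorphic SNPs remain: unusable locus")

  Z <- scale(raw[, keep, drop = FALSE])
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  colnames(Z) <- snp_ids[keep]
  new_pmr_panel(Z, snp_ids[keep], effect_allele[keep], other_allele[keep],
                pmin(freq[keep], 1 - freq[keep]))
}

#' Flip the allele orientation of a fraction of SNPs
#'
#' Re-orients randomly chosen SNP columns: an allele-count flip g -> 2 - g is,
#' after standardization, exactly a sign change of the column. Allele labels
#' are swapped for flipped SNPs. Used to probe robustness of genotype coding
#' conventions (the model's likelihood is invariant to joint flips up to the
#' sign of the pleiotropy estimate).
#'
#' @param panel a `pmr_panel`.
#' @param fraction fraction of SNPs to flip, in \[0, 1\]; exactly
#'   `round(fraction * p)` columns are flipped.
#' @param seed optional integer seed for the choice of columns.
#' @return A `pmr_panel` with flipped columns.
#' @export
flip_genotypes <- function(panel, fraction, seed = NULL) {
  stopifnot(inherits(panel, "pmr_panel"), fraction >= 0, fraction <= 1)
  k <- round(fraction * panel$p)
  if (k == 0) return(panel)
  idx <- with_seed_if(seed, sample.int(panel$p, k))
  panel$Z[, idx] <- -panel$Z[, idx]
  tmp <- panel$effect_allele[idx]
  panel$effect_allele[idx] <- panel$other_allele[idx]
  panel$other_allele[idx] <- tmp
  panel
}

## run expr under a temporary RNG seed when seed is non-NULL
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Bundle two panels and their phenotypes as individual-level data
#'
#' The expression-study panel and the GWAS panel must cover the same SNPs in
#' the same order and allele orientation. Expression and trait vectors are
#' centered and scaled to unit variance.
#'
#' @param panel_x `pmr_panel` for the expression study (n1 x p).
#' @param x numeric expression vector, length n1.
#' @param panel_y `pmr_panel` for the GWAS (n2 x p).
#' @param y numeric trait vector, length n2.
#' @return A list of class `pmr_individual_data`.
#' @export
individual_data <- function(panel_x, x, panel_y, y) {
  stopifnot(inherits(panel_x, "pmr_panel"), inherits(panel_y, "pmr_panel"))
  if (panel_x$p != panel_y$p || !identical(panel_x$snp_ids, panel_y$snp_ids))
    abort("expression and GWAS panels must cover identical SNPs in identical order")
  both <- !is.na(panel_x$effect_allele) & !is.na(panel_y$effect_allele)
  if (any(panel_x$effect_allele[both] != panel_y$effect_allele[both]))
    abort("allele orientation differs between panels; harmonize first")
  if (length(x) != panel_x$n) abort("length(x) must equal panel_x$n")
  if (length(y) != panel_y$n) abort("length(y) must equal panel_y$n")
  x <- drop(scale(x)); y <- drop(scale(y))
  structure(list(panel_x = panel_x, x = x, panel_y = panel_y, y = y),
            class = "pmr_individual_data")
}
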