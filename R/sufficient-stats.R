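#' Sufficient statistics of the joint PMR likelihood
#'
#' The marginal likelihood of the two-study model depends on the data only
#' through the p-dimensional cross-products assembled here: Cxx = Zx'Zx,
#' cx = Zx'x, sxx = x'x from the expression study, and Cyy = Zy'Zy,
#' cy = Zy'y, syy = y'y from the GWAS. They are the shared currency of the
#' individual-level and the summary-statistics input modes, and make the
#' cost of all downstream fitting independent of the cohort sizes.
#'
#' @param Cxx,Cyy p x p symmetric cross-product matrices.
#' @param cx,cy p-vectors of genotype-phenotype cross-products.
#' @param sxx,syy scalar phenotype sums of squares.
#' @param n1,n2 cohort sizes.
#' @param snp_ids SNP identifiers, length p.
#' @return An object of class `pmr_stats`.
#' @export
pmr_stats <- function(Cxx, cx, sxx, n1, Cyy, cy, syy, n2, snp_ids = NULL) {
  Cxx <- as.matrix(Cxx); Cyy <- as.matrix(Cyy)
  p <- length(cx)
  stopifnot(length(cy) == p, nrow(Cxx) == p, ncol(Cxx) == p,
            nrow(Cyy) == p, ncol(Cyy) == p, sxx > 0, syy > 0)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  ## symmetrize to remove roundoff skew
  Cxx <- (Cxx + t(Cxx)) / 2
  Cyy <- (Cyy + t(Cyy)) / 2
  structure(
    list(Cxx = Cxx, cx = as.numeric(cx), sxx = as.numeric(sxx), n1 = n1,
         Cyy = Cyy, cy = as.numeric(cy), syy = as.numeric(syy), n2 = n2,
         snp_ids = snp_ids, p = p),
    class = "pmr_stats"
  )
}

#' @export
print.pmr_stats <- function(x, ...) {
  cat("<pmr_stats> p = ", x$p, ", n1 = ", x$n1, ", n2 = ", x$n2, "\n", sep = "")
  invisible(x)
}

#' Compute sufficient statistics from individual-level data
#'
#' Exact cross-products of the standardized panels and phenotypes; the
#' symmetric matrices are symmetrized to remove floating-point skew.
#'
#' @param data a [individual_data()] object.
#' @return A [pmr_stats()] object.
#' @export
compute_sufficient_stats <- function(data) {
  stopifnot(inherits(data, "pmr_individual_data"))
  Zx <- data$panel_x$Z; Zy <- data$panel_y$Z
  pmr_stats(
    Cxx = crossprod(Zx), cx = drop(crossprod(Zx, data$x)),
    sxx = sum(data$x^2), n1 = nrow(Zx),
    Cyy = crossprod(Zy), cy = drop(crossprod(Zy, data$y)),
    syy = sum(data$y^2), n2 = nrow(Zy),
    snp_ids = data$panel_x$snp_ids
  )
}

#' Check numerical positive semidefiniteness of the cross-product matrices
#'
#' @param stats a `pmr_stats` object.
#' @param tol relative eigenvalue tolerance.
#' @return `stats`, invisibly; errors when a matrix is indefinite.
#' @export
validate_stats <- function(stats, tol = 1e-8) {
  stopifnot(inherits(stats, "pmr_stats"))
  for (nm in c("Cxx", "Cyy")) {
    ev <- eigen(stats[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(abs(ev), 1))
      abort(paste0(nm, " is not positive semidefinite"))
  }
  invisible(stats)
}

#' Serialize sufficient statistics to a key-value container on disk
#'
#' Fields are stored under the names `Cxx`, `cx`, `sxx`, `n1`, `Cyy`, `cy`,
#' `syy`, `n2`, `snp_ids`.
#'
#' @param stats a `pmr_stats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  stopifnot(inherits(stats, "pmr_stats"))
  saveRDS(stats[c("Cxx", "cx", "sxx", "n1", "Cyy", "cy", "syy", "n2",
                  "snp_ids")], path)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  s <- readRDS(path)
  pmr_stats(s$Cxx, s$cx, s$sxx, s$n1, s$Cyy, s$cy, s$syy, s$n2, s$snp_ids)
}
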