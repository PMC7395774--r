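#' Read genotypes from PLINK bed/bim/fam or VCF
#'
#' Returns allele counts with missingness preserved, plus SNP metadata with
#' 1-based coordinates. PLINK .bed files are decoded directly from their
#' 2-bit SNP-major encoding (counts of the A1 allele); VCF files are read
#' through the vcfR package (counts of the ALT allele), skipping
#' multiallelic records with a warning.
#'
#' @param path path to the `.bed` file (with `.bim`/`.fam` alongside) or to
#'   a `.vcf`/`.vcf.gz` file.
#' @param format `"plink_bed"` or `"vcf"`; guessed from the extension by
#'   default.
#' @return A list with `genotypes` (n x p matrix of 0/1/2/NA counts,
#'   individuals in file order) and `snps`, a tibble with columns `snp`,
#'   `chrom`, `pos`, `counted_allele`, `other_allele`.
#' @export
load_genotypes <- function(path, format = c("auto", "plink_bed", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path)) "plink_bed"
    else if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else abort("cannot guess genotype format; pass `format` explicitly")
  }
  if (format == "plink_bed") load_plink_bed(path) else load_vcf(path)
}

load_plink_bed <- function(bed_path) {
  stem <- sub("\\.bed$", "", bed_path)
  bim_path <- paste0(stem, ".bim")
  fam_path <- paste0(stem, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) abort(paste0("file not found: ", f))

  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "snp", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE)
  n <- nrow(fam)
  p <- nrow(bim)
  if (p == 0) abort("empty variant set in .bim")

  raw <- readBin(bed_path, "raw", n = 3 + ceiling(n / 4) * p)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    abort(paste0("not a PLINK .bed file (bad magic bytes): ", bed_path))
  if (raw[3] != as.raw(0x01))
    abort("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) < bytes_per_snp * p)
    abort(paste0("truncated .bed file: ", bed_path))

  ## 2-bit codes per individual: 00 = hom A1 (2), 01 = missing,
  ## 10 = het (1), 11 = hom A2 (0); counts are of the A1 allele
  lookup <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  ints <- as.integer(body[seq_len(bytes_per_snp * p)])
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  G <- matrix(lookup[as.character(codes)], nrow = 4 * bytes_per_snp)[
    seq_len(n), , drop = FALSE]
  colnames(G) <- bim$snp
  list(genotypes = G,
       snps = tibble(snp = bim$snp, chrom = bim$chrom, pos = bim$pos,
                     counted_allele = bim$a1, other_allele = bim$a2))
}

load_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warn(paste0(sum(multi), " multiallelic record(s) skipped"))
  keep <- which(!multi)
  if (length(keep) == 0) abort("empty variant set after filtering")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), 0L))
  }
  G <- t(apply(gt, 1, count_alt))
  G <- matrix(as.numeric(G), nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- fix[keep, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[no_id]
  list(genotypes = t(G),
       snps = tibble(snp = ids, chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]),
                     counted_allele = fix[keep, "ALT"],
                     other_allele = fix[keep, "REF"]))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on the heterozygote count conditional on the allele
#' counts, summing the probabilities of all outcomes no more likely than
#' the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom minor, het, hom major).
#' @return Exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab          # minor allele count
  if (n == 0 || n_a == 0 || n_a == 2 * n) return(1)
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  ## log-probabilities of the het count conditional on the allele counts
  logp <- hets * log(2) + lfactorial(n) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_a + hets) / 2) +
    lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  if (length(obs) == 0) return(1)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Per-SNP quality control on a raw genotype matrix
#'
#' Removes SNPs failing a call-rate, minor-allele-frequency or exact
#' Hardy-Weinberg threshold; the standard filters applied before a TWAS
#' analysis.
#'
#' @param genotypes n x p matrix of 0/1/2/NA allele counts.
#' @param snps tibble of SNP metadata (one row per column).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-4).
#' @param call_rate_min minimum genotype call rate (default 0.95).
#' @return A list with filtered `genotypes` and `snps`, plus `removed`, a
#'   tibble counting removals per criterion.
#' @export
qc_filter <- function(genotypes, snps, maf_min = 0.01, hwe_p_min = 1e-4,
                      call_rate_min = 0.95) {
  stopifnot(ncol(genotypes) == nrow(snps))
  if (ncol(genotypes) == 0) abort("empty panel")
  call_rate <- colMeans(!is.na(genotypes))
  freq <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hwe <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[!is.na(genotypes[, j]), j]
    counts <- c(sum(g == 2), sum(g == 1), sum(g == 0))
    if (freq[j] > 0.5) counts <- rev(counts)
    hwe_exact_p(counts[1], counts[2], counts[3])
  }, 0)
  fail_cr <- call_rate < call_rate_min
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- hwe < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  removed <- tibble(criterion = c("call_rate", "maf", "hwe"),
                    n_removed = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe)))
  if (!any(keep)) abort("all SNPs removed by QC")
  list(genotypes = genotypes[, keep, drop = FALSE],
       snps = snps[keep, , drop = FALSE],
       removed = removed)
}

#' Read gene annotation from BED or GFF3
#'
#' BED input (0-based, half-open) is converted to the internal 1-based
#' inclusive convention; GFF3 is already 1-based inclusive. Requires the
#' rtracklayer package.
#'
#' @param path annotation file (`.bed`, `.gff`, `.gff3`).
#' @param format override the extension-based format guess.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `tes`, `strand`
#'   (1-based inclusive, `tss <= tes`).
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "bed" else "gff3"
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("reading annotation requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  ids <- if (format == "bed") gr$name
  else dplyr::coalesce(gr$ID, gr$Name, as.character(seq_along(gr)))
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = GenomicRanges::start(gr),   # rtracklayer converts BED to 1-based
    tes = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Select SNPs in the cis-window of a gene
#'
#' SNPs within `window_bp` of the gene body: positions in
#' \[tss - window_bp, tes + window_bp\], inclusive on both ends, on the
#' gene's chromosome.
#'
#' @param gene one-row data frame or list with `chrom`, `tss`, `tes`.
#' @param snps tibble with `chrom` and `pos` (1-based).
#' @param window_bp flank size in base pairs (default 1e5).
#' @return Integer indices into `snps`.
#' @export
extract_cis_window <- function(gene, snps, window_bp = 1e5) {
  stopifnot(window_bp >= 0)
  lo <- gene$tss - window_bp
  hi <- gene$tes + window_bp
  which(snps$chrom == gene$chrom & snps$pos >= lo & snps$pos <= hi)
}

#' Transcriptome-wide association scan
#'
#' For each annotated gene: extracts the cis-window in both studies,
#' intersects SNPs, applies QC, harmonizes allele orientation (the counted
#' allele is the minor allele as defined in the GWAS cohort), standardizes,
#' builds sufficient statistics and runs [analyze_gene()]. Genes that fail
#' (no shared SNPs, QC removes everything, fit errors) are flagged, never
#' fatal.
#'
#' @param geno_x,geno_y outputs of [load_genotypes()] for the expression
#'   study and the GWAS.
#' @param expression numeric matrix of expression values, genes x samples,
#'   with rownames matching `annotations$gene_id`.
#' @param phenotype numeric trait vector for the GWAS cohort (pre-
#'   residualized on covariates if desired; see `covariates`).
#' @param annotations tibble from [read_gene_annotation()].
#' @param covariates optional numeric matrix of GWAS covariates projected
#'   out of the phenotype by least squares before standardization.
#' @param window_bp,maf_min,hwe_p_min,call_rate_min QC and window settings.
#' @param bonferroni_alpha family-wise level for the significance flags.
#' @param opts an [em_options()].
#' @return A tibble with one row per gene (`gene_id`, `p` SNP count,
#'   `alpha_hat`, `p_alpha`, `gamma_hat`, `p_gamma`, log-likelihoods,
#'   convergence flags, `sig_alpha`/`sig_gamma` Bonferroni flags, `note`),
#'   with attributes `lambda_alpha`, `lambda_gamma` and
#'   `bonferroni_threshold`.
#' @export
run_twas_scan <- function(geno_x, geno_y, expression, phenotype, annotations,
                          covariates = NULL, window_bp = 1e5, maf_min = 0.01,
                          hwe_p_min = 1e-4, call_rate_min = 0.95,
                          bonferroni_alpha = 0.05, opts = em_options()) {
  if (!is.null(covariates)) {
    phenotype <- stats::resid(stats::lm(phenotype ~ as.matrix(covariates)))
  }
  phenotype <- drop(scale(phenotype))

  rows <- purrr::map(seq_len(nrow(annotations)), function(i) {
    gene <- annotations[i, ]
    skip <- function(note) tibble(
      gene_id = gene$gene_id, p = 0L, alpha_hat = NA_real_,
      gamma_hat = NA_real_, p_alpha = NA_real_, p_gamma = NA_real_,
      loglik_full = NA_real_, loglik_alpha0 = NA_real_,
      loglik_gamma0 = NA_real_, converged_full = NA, note = note)

    if (!gene$gene_id %in% rownames(expression))
      return(skip("skipped: no expression"))

    ix <- extract_cis_window(gene, geno_x$snps, window_bp)
    iy <- extract_cis_window(gene, geno_y$snps, window_bp)
    shared <- intersect(geno_x$snps$snp[ix], geno_y$snps$snp[iy])
    if (length(shared) == 0) return(skip("skipped: no shared SNPs"))

    out <- tryCatch({
      jx <- match(shared, geno_x$snps$snp)
      jy <- match(shared, geno_y$snps$snp)
      qx <- qc_filter(geno_x$genotypes[, jx, drop = FALSE],
                      geno_x$snps[jx, ], maf_min, hwe_p_min, call_rate_min)
      qy <- qc_filter(geno_y$genotypes[, jy, drop = FALSE],
                      geno_y$snps[jy, ], maf_min, hwe_p_min, call_rate_min)
      shared2 <- intersect(qx$snps$snp, qy$snps$snp)
      if (length(shared2) == 0) return(skip("skipped: QC removed all SNPs"))
      jx2 <- match(shared2, qx$snps$snp)
      jy2 <- match(shared2, qy$snps$snp)

      gx <- qx$genotypes[, jx2, drop = FALSE]
      gy <- qy$genotypes[, jy2, drop = FALSE]
      sx_meta <- qx$snps[jx2, ]
      sy_meta <- qy$snps[jy2, ]
      ## align counted alleles between studies before orientation
      disagree <- sx_meta$counted_allele != sy_meta$counted_allele
      ok <- !disagree |
        (sx_meta$counted_allele == sy_meta$other_allele &
           sx_meta$other_allele == sy_meta$counted_allele)
      gx[, disagree & ok] <- 2 - gx[, disagree & ok, drop = FALSE]
      if (any(!ok)) {
        gx <- gx[, ok, drop = FALSE]; gy <- gy[, ok, drop = FALSE]
        sy_meta <- sy_meta[ok, ]
      }
      if (ncol(gx) == 0) return(skip("skipped: incompatible alleles"))

      ## minor allele defined in the GWAS data
      freq_y <- colMeans(gy, na.rm = TRUE) / 2
      py <- standardize_panel(gy, snp_ids = sy_meta$snp,
                              effect_allele = sy_meta$counted_allele,
                              other_allele = sy_meta$other_allele,
                              ref_freq = freq_y)
      keep_x <- match(py$snp_ids, sy_meta$snp)
      px <- standardize_panel(gx[, keep_x, drop = FALSE],
                              snp_ids = py$snp_ids,
                              effect_allele = sy_meta$counted_allele[keep_x],
                              other_allele = sy_meta$other_allele[keep_x],
                              ref_freq = freq_y[keep_x])
      common <- intersect(px$snp_ids, py$snp_ids)
      if (length(common) == 0) return(skip("skipped: monomorphic locus"))
      kx <- match(common, px$snp_ids); ky <- match(common, py$snp_ids)

      expr <- as.numeric(expression[gene$gene_id, ])
      x <- drop(scale(expr)); y <- phenotype
      st <- pmr_stats(crossprod(px$Z[, kx, drop = FALSE]),
                      drop(crossprod(px$Z[, kx, drop = FALSE], x)), sum(x^2),
                      px$n,
                      crossprod(py$Z[, ky, drop = FALSE]),
                      drop(crossprod(py$Z[, ky, drop = FALSE], y)), sum(y^2),
                      py$n, common)
      assoc <- analyze_gene(st, opts, gene_id = gene$gene_id)
      dplyr::mutate(
        dplyr::select(tidy(assoc), -dplyr::any_of(c("n1", "n2",
                                                    "converged_alpha0",
                                                    "converged_gamma0"))),
        note = NA_character_)
    }, error = function(e) skip(paste0("error: ", conditionMessage(e))))
    out
  })
  res <- dplyr::bind_rows(rows)

  n_tested <- sum(!is.na(res$p_alpha))
  thr <- if (n_tested > 0) bonferroni_alpha / n_tested else NA_real_
  res <- dplyr::mutate(
    res,
    sig_alpha = !is.na(.data$p_alpha) & .data$p_alpha < thr,
    sig_gamma = !is.na(.data$p_gamma) & .data$p_gamma < thr
  )
  attr(res, "lambda_alpha") <-
    if (n_tested > 0) genomic_control(res$p_alpha[!is.na(res$p_alpha)]) else NA_real_
  attr(res, "lambda_gamma") <-
    if (n_tested > 0) genomic_control(res$p_gamma[!is.na(res$p_gamma)]) else NA_real_
  attr(res, "bonferroni_threshold") <- thr
  res
}
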