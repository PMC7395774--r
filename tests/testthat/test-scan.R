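## write a tiny PLINK bed/bim/fam trio by hand-encoding the 2-bit format
write_plink_fixture <- function(dir, genotypes, chrom, pos, a1, a2,
                                stem = "toy") {
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  bim <- data.frame(chrom, paste0("rs", seq_len(p)), 0, pos, a1, a2)
  write.table(bim, file.path(dir, paste0(stem, ".bim")), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  fam <- data.frame(paste0("F", 1:n), paste0("I", 1:n), 0, 0, 0, -9)
  write.table(fam, file.path(dir, paste0(stem, ".fam")), sep = " ",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  code <- function(g) if (is.na(g)) 1L else c(`0` = 3L, `1` = 2L, `2` = 0L)[
    as.character(g)]
  con <- file(file.path(dir, paste0(stem, ".bed")), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(p)) {
    codes <- vapply(genotypes[, j], code, 0L)
    length(codes) <- 4 * ceiling(n / 4)
    codes[is.na(codes)] <- 0L
    bytes <- colSums(matrix(codes, 4) * c(1L, 4L, 16L, 64L))
    writeBin(as.raw(bytes), con)
  }
  close(con)
  file.path(dir, paste0(stem, ".bed"))
}

test_that("PLINK bed decoding matches the hand-encoded bytes", {
  dir <- withr::local_tempdir()
  G <- rbind(c(0, 1, 2), c(2, NA, 1), c(1, 1, 0))
  bed <- write_plink_fixture(dir, G, chrom = c(1, 1, 2),
                             pos = c(100, 200, 300),
                             a1 = c("A", "C", "G"), a2 = c("G", "T", "A"))
  got <- load_genotypes(bed)
  expect_equal(unname(got$genotypes), G)
  expect_equal(got$snps$pos, c(100L, 200L, 300L))
  expect_equal(got$snps$counted_allele, c("A", "C", "G"))
  expect_error(load_genotypes(file.path(dir, "missing.bed")), "not found")
})

test_that("VCF records load as ALT counts and multiallelics are skipped", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "1\t300\trs3\tT\tC\t.\tPASS\t.\tGT\t./.\t1|1\t0/1"
  ), vcf)
  expect_warning(got <- load_genotypes(vcf), "multiallelic")
  expect_equal(nrow(got$snps), 2)
  expect_equal(got$snps$snp, c("rs1", "rs3"))
  expect_equal(unname(got$genotypes[, 1]), c(0, 1, 2))
  expect_equal(unname(got$genotypes[, 2]), c(NA, 2, 1))
})

test_that("exact HWE test matches reference values and QC filters apply", {
  ## (AA, Aa, aa) = (25, 50, 25) is exactly at equilibrium
  expect_gt(hwe_exact_p(25, 50, 25), 0.9)
  ## gross heterozygote excess is rejected
  expect_lt(hwe_exact_p(0, 100, 0), 1e-10)
  ## compare against the chi-square approximation on a moderate case
  chisq_p <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    q <- (2 * naa + nab) / (2 * n)
    e <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
    stats::pchisq(sum((c(naa, nab, nbb) - e)^2 / e), 1, lower.tail = FALSE)
  }
  expect_equal(hwe_exact_p(30, 40, 30), chisq_p(30, 40, 30),
               tolerance = 0.15)

  withr::with_seed(80, {
    G <- cbind(
      ok = rbinom(200, 2, 0.3),
      rare = rbinom(200, 2, 0.004),
      patchy = ifelse(runif(200) < 0.1, NA, rbinom(200, 2, 0.4)),
      hwe_bad = rep(1, 200)
    )
  })
  snps <- tibble::tibble(snp = colnames(G), chrom = "1",
                         pos = 1:4, counted_allele = "A", other_allele = "G")
  q <- qc_filter(G, snps)
  expect_true("ok" %in% q$snps$snp)
  expect_false("rare" %in% q$snps$snp)       # MAF < 0.01
  expect_false("patchy" %in% q$snps$snp)     # call rate < 0.95
  expect_false("hwe_bad" %in% q$snps$snp)    # all-het fails exact HWE
  expect_equal(sum(q$removed$n_removed > 0), 3)
  ## a clean SNP passing all thresholds is retained
  expect_error(qc_filter(G[, "rare", drop = FALSE], snps[2, ]), "all SNPs")
})

test_that("cis-window extraction is 1-based inclusive on both ends", {
  gene <- list(gene_id = "g", chrom = "1", tss = 500000L, tes = 600000L)
  snps <- tibble::tibble(
    chrom = c("1", "1", "1", "1", "2"),
    pos = c(400000L, 399999L, 700000L, 700001L, 500000L))
  idx <- extract_cis_window(gene, snps, window_bp = 1e5)
  expect_true(1 %in% idx)    # exactly at tss - window
  expect_false(2 %in% idx)   # one base outside
  expect_true(3 %in% idx)    # exactly at tes + window
  expect_false(4 %in% idx)   # one base outside
  expect_false(5 %in% idx)   # other chromosome
})

test_that("BED annotation converts to 1-based inclusive coordinates", {
  skip_if_not_installed("rtracklayer")
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  ## BED line chr1 999 2000 covers 1-based [1000, 2000]
  writeLines("chr1\t999\t2000\tgeneA\t0\t+", bed)
  ann <- read_gene_annotation(bed)
  expect_equal(ann$tss, 1000L)
  expect_equal(ann$tes, 2000L)
  expect_equal(ann$gene_id, "geneA")
})

## small synthetic two-study dataset with raw allele counts plus
## annotation, for end-to-end scans
scan_fixture <- function(seed = 1, n_genes = 8, p_per_gene = 12,
                         n1 = 150, n2 = 400, causal = c(2, 5)) {
  p <- n_genes * p_per_gene
  raw_geno <- function(n, maf, seed) {
    withr::with_seed(seed, {
      G <- matrix(0L, n, p)
      for (h in 1:2)
        G <- G + (matrix(rnorm(n * p), n, p) <
                    matrix(qnorm(maf), n, p, byrow = TRUE))
      G
    })
  }
  withr::with_seed(seed, maf <- runif(p, 0.15, 0.5))
  Gx <- raw_geno(n1, maf, seed + 1)
  Gy <- raw_geno(n2, maf, seed + 2)
  colnames(Gx) <- colnames(Gy) <- paste0("rs", seq_len(p))
  pos <- seq_len(p) * 1000L
  snps <- tibble::tibble(snp = colnames(Gx), chrom = "1", pos = pos,
                         counted_allele = "A", other_allele = "G")
  ann <- tibble::tibble(
    gene_id = paste0("gene", seq_len(n_genes)), chrom = "1",
    tss = (seq_len(n_genes) - 1) * p_per_gene * 1000L + 2000L,
    tes = (seq_len(n_genes) - 1) * p_per_gene * 1000L + 9000L,
    strand = "+")
  expr <- matrix(NA_real_, n_genes, n1, dimnames = list(ann$gene_id, NULL))
  y <- numeric(n2)
  Zx <- scale(Gx); Zy <- scale(Gy)
  withr::with_seed(seed + 3, {
    for (g in seq_len(n_genes)) {
      idx <- extract_cis_window(ann[g, ], snps, window_bp = 2000)
      beta <- simulate_beta(length(idx), 0.4)
      expr[g, ] <- drop(Zx[, idx] %*% beta) + rnorm(n1, 0, sqrt(0.6))
      if (g %in% causal) y <- y + 0.6 * drop(Zy[, idx] %*% beta)
    }
    y <- y + rnorm(n2)
  })
  list(geno_x = list(genotypes = Gx, snps = snps),
       geno_y = list(genotypes = Gy, snps = snps),
       expression = expr, phenotype = y, annotations = ann)
}

test_that("TWAS scan ranks truly causal genes first and flags failures", {
  fx <- scan_fixture(seed = 90)
  res <- run_twas_scan(fx$geno_x, fx$geno_y, fx$expression, fx$phenotype,
                       fx$annotations, window_bp = 2000)
  expect_equal(nrow(res), 8)
  ranked <- res$gene_id[order(res$p_alpha)]
  expect_setequal(ranked[1:2], c("gene2", "gene5"))
  expect_true(all(res$p[!is.na(res$p_alpha)] > 0))
  expect_true(is.finite(attr(res, "lambda_alpha")))
  expect_equal(attr(res, "bonferroni_threshold"), 0.05 / 8)

  ## a gene with no cis-SNPs in the GWAS panel is skipped, not fatal
  ann2 <- fx$annotations
  ann2$chrom[3] <- "9"
  res2 <- run_twas_scan(fx$geno_x, fx$geno_y, fx$expression, fx$phenotype,
                        ann2, window_bp = 2000)
  expect_match(res2$note[3], "no shared SNPs")
  expect_equal(sum(is.na(res2$p_alpha)), 1)
})

test_that("scan under a permuted phenotype is globally null", {
  fx <- scan_fixture(seed = 91, causal = integer(0))
  res <- run_twas_scan(fx$geno_x, fx$geno_y, fx$expression, fx$phenotype,
                       fx$annotations, window_bp = 2000)
  expect_true(all(res$p_alpha > 1e-3, na.rm = TRUE))
  expect_false(any(res$sig_alpha, na.rm = TRUE))
})
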