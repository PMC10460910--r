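test_that("the null REML reduces to OLS on an identity GRM", {
  set.seed(2)
  n <- 200
  y <- rnorm(n)
  grm <- rel_matrix(diag(n), paste0("i", 1:n), "GRM")
  fit <- fit_null_lmm(y, grm = grm)
  # only the total variance is identified; it equals the OLS residual MS
  total <- fit$sigma2_g + fit$sigma2_e
  expect_equal(total, sum((y - mean(y))^2) / (n - 1), tolerance = 1e-4)

  # sigma2_g near zero when the GRM carries no signal by construction
  co <- small_cohort(n = 500, m = 300, h2 = 0, n_qtl = 0, seed = 41)
  g <- grm_vanraden(co$genotypes)
  f0 <- fit_null_lmm(co$phenotypes$phenotype, grm = g)
  expect_lte(f0$sigma2_g, 0.05)

  expect_identical(glance(fit), glance(fit_null_lmm(y, grm = grm)))
})

test_that("scan statistics match the closed-form least-squares oracle", {
  y <- c(0, 0, 1, 1)
  g <- c(0, 1, 1, 2)
  geno <- toy_geno(matrix(g, ncol = 1))
  grm <- rel_matrix(diag(4), paste0("i", 1:4), "GRM")
  nf <- fit_null_lmm(y, grm = grm)
  sc <- gwas_scan(geno, nf)
  expect_equal(sc$beta, 0.5, tolerance = 1e-6)  # Sxy = 1, Sxx = 2

  # general equivalence: identity GRM, p-values equal the least-squares
  # Wald test with the null-model residual variance
  set.seed(5)
  n <- 120; m <- 40
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  yq <- rnorm(n)
  geno2 <- toy_geno(G)
  nf2 <- fit_null_lmm(yq, grm = rel_matrix(diag(n), paste0("i", 1:n), "GRM"))
  sc2 <- gwas_scan(geno2, nf2)
  sigma2 <- nf2$sigma2_g + nf2$sigma2_e
  oracle <- sapply(seq_len(m), function(j) {
    x <- G[, j]
    xc <- x - mean(x); yc <- yq - mean(yq)
    beta <- sum(xc * yc) / sum(xc^2)
    z <- beta / sqrt(sigma2 / sum(xc^2))
    2 * pnorm(-abs(z))
  })
  expect_equal(sc2$p, oracle, tolerance = 1e-8)

  # duplicated SNP gives identical statistics
  geno3 <- toy_geno(cbind(G[, 1], G[, 1]))
  sc3 <- gwas_scan(geno3, nf2)
  expect_equal(sc3$p[1], sc3$p[2])
})

test_that("null p-values are uniform under permuted phenotypes", {
  co <- small_cohort(n = 200, m = 1000, h2 = 0.4, n_qtl = 10, seed = 51,
                     ld_rho = 0.2)
  set.seed(52)
  yp <- sample(co$phenotypes$phenotype)
  grm <- grm_vanraden(co$genotypes)
  nf <- fit_null_lmm(yp, grm = grm)
  sc <- gwas_scan(co$genotypes, nf)
  ks <- stats::ks.test(sc$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("genomic inflation follows its definition", {
  expect_equal(suppressWarnings(genomic_inflation(rep(0.5, 200))), 1)
  set.seed(6)
  expect_true(abs(genomic_inflation(runif(10000)) - 1) < 0.05)
  p <- runif(5000)
  expect_gt(genomic_inflation(p / 2), genomic_inflation(p))
  suppressWarnings(expect_error(genomic_inflation(c(0, 0.5)), "0, 1"))
})

test_that("Bonferroni thresholds are plain division", {
  expect_equal(signif(bonferroni_threshold(0.05, 447630), 2), 1.1e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
})

test_that("permutation thresholds follow the documented min-p quantile rule", {
  # independent SNPs, unstructured samples: use an identity GRM so the
  # min-p distribution can be compared with the Sidak closed form
  set.seed(61)
  n <- 150; m <- 10
  geno <- toy_geno(sapply(1:m, function(j) rbinom(n, 2, 0.4)))
  y <- rnorm(n)
  idg <- rel_matrix(diag(n), paste0("i", 1:n), "GRM")
  pt <- permutation_threshold(geno, y, grm = idg, n_perm = 2000, seed = 62)
  # documented rule: type-7 quantile of the per-permutation minimum p
  expect_equal(pt$threshold,
               unname(quantile(pt$min_p, 0.05, type = 7)))
  # independent oracle: plain OLS scan over the same permutation stream
  G <- geno$values
  Xc <- scale(G, scale = FALSE)
  sxx <- colSums(Xc^2)
  set.seed(62)
  minp <- replicate(2000, {
    yp <- sample(y); yc <- yp - mean(yp)
    beta <- colSums(Xc * yc) / sxx
    z <- beta / sqrt(stats::var(yp) / sxx)
    min(2 * pnorm(-abs(z)))
  })
  expect_equal(pt$threshold, unname(quantile(minp, 0.05, type = 7)),
               tolerance = 1e-10)
  sidak <- 1 - (1 - 0.05)^(1 / m)
  expect_lt(abs(pt$threshold - sidak), 0.3 * sidak)

  pt2 <- permutation_threshold(geno, y, grm = idg, n_perm = 2, seed = 9)
  pt3 <- permutation_threshold(geno, y, grm = idg, n_perm = 2, seed = 9)
  expect_identical(pt2$threshold, pt3$threshold)
})

test_that("gene annotation respects the +-50 kb flank rule", {
  hits <- tibble::tibble(chrom = "chr1", pos = 100000L, id = "snp1")
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(140000L, 151000L),
                        end = c(160000L, 160000L),
                        gene = c("NEAR", "FAR"))
  out <- annotate_hits(hits, ann, flank = 50000)
  expect_equal(out$gene, "NEAR")

  # flank 0: only the gene whose interval contains the SNP
  inside <- annotate_hits(tibble::tibble(chrom = "chr1", pos = 150000L,
                                         id = "s"),
                          ann, flank = 0)
  expect_equal(inside$gene, "NEAR")

  expect_warning(
    none <- annotate_hits(tibble::tibble(chrom = "chrX", pos = 1L, id = "s"),
                          ann),
    "skipped"
  )
  expect_equal(nrow(none), 0L)
})

test_that("annotations read from BED become 1-based inclusive intervals", {
  bed <- file.path(withr::local_tempdir(), "genes.bed")
  writeLines("chr1\t139999\t160000\tGENE1", bed)
  gr <- read_annotations(bed)
  expect_equal(GenomicRanges::start(gr), 140000L)
  expect_equal(GenomicRanges::end(gr), 160000L)
  hits <- tibble::tibble(chrom = "chr1", pos = 100000L, id = "snp1")
  expect_equal(annotate_hits(hits, gr)$gene, "GENE1")
})
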