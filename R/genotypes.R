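#' Construct a genotype matrix container
#'
#' Holds additive-coded dosages (0/1/2, `NA` = missing; real-valued dosages
#' in `[0, 2]` are accepted after imputation) together with a variant table
#' and a sample table. Dimensions must agree and positions must be strictly
#' increasing within each chromosome.
#'
#' @param values n_samples x m_snps numeric matrix.
#' @param variants Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   and optionally `maf` (recomputed if absent).
#' @param samples Tibble with column `id` (plus optional `sex`,
#'   `phenotype`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, variants, samples) {
  values <- as.matrix(values)
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  if (ncol(values) != nrow(variants)) {
    ta_stop("variant table and genotype columns disagree")
  }
  if (nrow(values) != nrow(samples)) {
    ta_stop("sample table and genotype rows disagree")
  }
  obs <- values[!is.na(values)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 2)) {
    ta_stop("genotype codes must lie in [0, 2] or be NA")
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      ta_stop(sprintf("positions not strictly increasing on %s", ch),
              class = "traitarch_unsorted_error")
    }
  }
  if (!("maf" %in% names(variants))) variants$maf <- compute_maf(values)
  structure(list(values = values, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$variants$chrom))))
  invisible(x)
}

compute_maf <- function(values) {
  p <- colMeans(values, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

# ---- PLINK bed/bim/fam ------------------------------------------------------

# 2-bit SNP-major codes: 00 = hom A1 (dosage 2 of A1), 10 = het,
# 11 = hom A2 (dosage 0), 01 = missing. A1 is the counted (alt) allele.
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' The bed file is SNP-major with the standard magic bytes; A1 in the bim is
#' the counted (alt) allele, so dosages round-trip. The fam phenotype column
#' uses the PLINK case/control dialect 1 = control, 2 = case, -9 = missing;
#' sex is 1 = male, 2 = female, 0 = unknown. Non-integer (imputed) dosages
#' cannot be represented and raise an error.
#'
#' @param geno A `genotype_matrix`.
#' @param prefix Output path prefix (writes `<prefix>.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  G <- geno$values
  obs <- G[!is.na(G)]
  if (any(obs != round(obs))) {
    ta_stop("PLINK bed cannot encode non-integer dosages")
  }
  n <- nrow(G); m <- ncol(G)
  v <- geno$variants
  bim <- data.frame(chrom = v$chrom, id = v$id, cm = 0, pos = v$pos,
                    a1 = v$alt, a2 = v$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  s <- geno$samples
  sex_col <- if (!is.null(s$sex)) ifelse(is.na(s$sex), 0L, 2L - s$sex) else 0L
  phe_col <- if (!is.null(s$phenotype)) {
    ifelse(is.na(s$phenotype), -9L, s$phenotype + 1L)
  } else -9L
  fam <- data.frame(fid = s$id, iid = s$id, father = 0, mother = 0,
                    sex = sex_col, phenotype = phe_col)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  code <- matrix(0L, nrow = n, ncol = m)          # 2-bit value per cell
  code[G == 2] <- 0L; code[G == 1] <- 2L; code[G == 0] <- 3L
  code[is.na(G)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  pad <- 4L * bytes_per_snp - n
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep(3L, pad))              # pad with hom-A2
    quads <- matrix(cj, nrow = 4L)
    byte <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix Path prefix of the fileset.
#' @return A `genotype_matrix`. Unsorted bim positions within a chromosome
#'   raise an error (no silent re-sort).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "phenotype"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(raw[1:3], .bed_magic)) {
    ta_stop("not a SNP-major PLINK bed file (bad magic bytes)")
  }
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) != bytes_per_snp * m) {
    ta_stop("bed payload size disagrees with bim/fam dimensions")
  }
  quads <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  G <- matrix(NA_real_, nrow = n, ncol = m)
  lookup <- c(2, NA, 1, 0)                        # 2-bit code -> dosage
  for (j in seq_len(m)) {
    cells <- quads[, (j - 1L) * bytes_per_snp + seq_len(bytes_per_snp)]
    G[, j] <- lookup[cells[seq_len(n)] + 1L]
  }
  rownames(G) <- as.character(fam$iid)
  variants <- tibble(chrom = bim$chrom, pos = bim$pos, id = bim$id,
                     ref = bim$a2, alt = bim$a1)
  samples <- tibble(
    id = as.character(fam$iid),
    sex = ifelse(fam$sex %in% c(1L, 2L), 2L - fam$sex, NA_integer_),
    phenotype = ifelse(fam$phenotype %in% c(1L, 2L), fam$phenotype - 1L,
                       NA_integer_)
  )
  genotype_matrix(G, variants, samples)
}

# ---- VCF --------------------------------------------------------------------

#' Write genotypes (or phased haplotypes) as a VCF 4.2 text file
#'
#' Integer dosages are emitted as unphased `0/0`, `0/1`, `1/1` genotypes
#' (`./.` for missing). If `haplotypes` is supplied, phased `a|b` genotypes
#' are written instead and must be consistent with the dosages.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output file.
#' @param haplotypes Optional `haplotype_set` for phased output.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, haplotypes = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  G <- geno$values
  n <- nrow(G); m <- ncol(G)
  v <- geno$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=traitarch",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples$id), collapse = "\t")
  )
  if (is.null(haplotypes)) {
    gt <- matrix("./.", nrow = n, ncol = m)
    gt[!is.na(G) & G == 0] <- "0/0"
    gt[!is.na(G) & G == 1] <- "0/1"
    gt[!is.na(G) & G == 2] <- "1/1"
  } else {
    H <- haplotypes$matrix
    a <- H[seq(1L, 2L * n, 2L), , drop = FALSE]
    b <- H[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(a, "|", b), nrow = n, ncol = m)
  }
  rows <- vapply(seq_len(m), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix (and optionally haplotypes)
#'
#' Parses via vcfR. Multi-allelic records raise an error; `./.` maps to the
#' missing sentinel. If every genotype is phased, the haplotype matrix is
#' returned alongside.
#'
#' @param path VCF file (text or bgzipped).
#' @return A list with `genotypes` (a `genotype_matrix`) and `haplotypes`
#'   (a `haplotype_set`, or `NULL` when any genotype is unphased).
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    ta_stop("multi-allelic VCF records are not supported")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # rows = variants, cols = samples
  alleles <- function(x) {
    a <- t(vapply(strsplit(x, "[/|]"), function(p) {
      if (length(p) != 2L) c(NA_integer_, NA_integer_)
      else suppressWarnings(as.integer(p))
    }, integer(2)))
    a
  }
  m <- nrow(gt); n <- ncol(gt)
  G <- matrix(NA_real_, nrow = n, ncol = m)
  H1 <- matrix(NA_integer_, nrow = n, ncol = m)
  H2 <- matrix(NA_integer_, nrow = n, ncol = m)
  phased_all <- TRUE
  for (j in seq_len(m)) {
    al <- alleles(gt[j, ])
    G[, j] <- al[, 1] + al[, 2]
    H1[, j] <- al[, 1]; H2[, j] <- al[, 2]
    if (any(grepl("/", gt[j, ], fixed = TRUE))) phased_all <- FALSE
  }
  rownames(G) <- colnames(gt)
  variants <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                 paste0("snp_", seq_len(m)), fix$ID),
                     ref = fix$REF, alt = fix$ALT)
  geno <- genotype_matrix(G, variants, tibble(id = colnames(gt)))
  haps <- NULL
  if (phased_all && !anyNA(H1)) {
    HM <- matrix(0L, nrow = 2L * n, ncol = m)
    HM[seq(1L, 2L * n, 2L), ] <- H1
    HM[seq(2L, 2L * n, 2L), ] <- H2
    haps <- structure(
      list(matrix = HM, positions = variants$pos, chromosome = variants$chrom,
           freq = colMeans(HM), group = "all"),
      class = "haplotype_set"
    )
  }
  list(genotypes = geno, haplotypes = haps)
}

#' Read or write genotypes, dispatching on format
#'
#' @param path File path (VCF) or fileset prefix (PLINK).
#' @param format `"plink"` or `"vcf"`.
#' @export
read_genotypes <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") read_plink(path) else read_vcf(path)$genotypes
}

#' @rdname read_genotypes
#' @param geno A `genotype_matrix`.
#' @export
write_genotypes <- function(geno, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") write_plink(geno, path) else write_vcf(geno, path)
}

# ---- quality control --------------------------------------------------------

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided conditional exact test: given the allele counts, the p-value is
#' the summed probability of every heterozygote count no more probable than
#' the observed one. Monomorphic sites return 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    ta_stop("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) ta_stop("need at least one genotyped sample")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1)
  # feasible heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized log-probability conditional on the allele counts; terms
  # constant in h drop out after normalization
  logp <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    h * log(2) -
      (lgamma(rare_hom + 1) + lgamma(h + 1) + lgamma(common_hom + 1))
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Apply marker and sample quality-control filters
#'
#' Filters are applied in a fixed, documented order: sample call rate, then
#' SNP call rate, then minor allele frequency (recomputed after sample
#' removal), then the Hardy-Weinberg exact test on all remaining samples.
#' Each removed SNP is attributed to the first filter that removes it.
#'
#' @param geno A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param snp_call_min Minimum per-SNP call rate (default 0.95).
#' @param sample_call_min Minimum per-sample call rate (default 0.90).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level
#'   (default 1e-6).
#' @return A list with `genotypes` (filtered `genotype_matrix`) and
#'   `report` (a `qc_report`).
#' @export
qc_filter <- function(geno, maf_min = 0.05, snp_call_min = 0.95,
                      sample_call_min = 0.90, hwe_alpha = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  check_fraction(maf_min, "maf_min", 0, 0.5)
  check_fraction(snp_call_min, "snp_call_min")
  check_fraction(sample_call_min, "sample_call_min")
  check_fraction(hwe_alpha, "hwe_alpha", 0, 1, lo_open = TRUE)
  n_in <- nrow(geno$values); m_in <- ncol(geno$values)
  G <- geno$values

  sample_cr <- rowMeans(!is.na(G))
  keep_s <- sample_cr >= sample_call_min
  G <- G[keep_s, , drop = FALSE]

  snp_cr <- colMeans(!is.na(G))
  rm_call <- snp_cr < snp_call_min

  maf <- compute_maf(G)
  rm_maf <- !rm_call & (is.na(maf) | maf < maf_min)

  rm_hwe <- rep(FALSE, ncol(G))
  todo <- which(!rm_call & !rm_maf)
  if (length(todo)) {
    Gi <- round(G[, todo, drop = FALSE])
    hwe_p <- vapply(seq_along(todo), function(k) {
      g <- Gi[, k]; g <- g[!is.na(g)]
      hwe_exact_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
    }, numeric(1))
    rm_hwe[todo] <- hwe_p < hwe_alpha
  }

  keep_m <- !(rm_call | rm_maf | rm_hwe)
  if (!any(keep_m)) ta_stop("all SNPs removed by QC filters")
  out <- genotype_matrix(
    G[, keep_m, drop = FALSE],
    mutate(geno$variants[keep_m, ], maf = maf[keep_m]),
    geno$samples[keep_s, ]
  )
  report <- structure(list(
    n_samples_in = n_in, n_samples_out = sum(keep_s),
    n_snps_in = m_in, n_snps_out = sum(keep_m),
    removed = c(sample_call = n_in - sum(keep_s),
                snp_call = sum(rm_call), maf = sum(rm_maf),
                hwe = sum(rm_hwe)),
    thresholds = c(maf_min = maf_min, snp_call_min = snp_call_min,
                   sample_call_min = sample_call_min, hwe_alpha = hwe_alpha)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> samples %d -> %d; SNPs %d -> %d\n",
              x$n_samples_in, x$n_samples_out, x$n_snps_in, x$n_snps_out))
  cat(sprintf("  removed: sample call rate %d | SNP call rate %d | MAF %d | HWE %d\n",
              x$removed["sample_call"], x$removed["snp_call"],
              x$removed["maf"], x$removed["hwe"]))
  invisible(x)
}

#' Tidy a QC report into one row per filter
#' @param x A `qc_report`.
#' @param ... Unused.
#' @export
tidy.qc_report <- function(x, ...) {
  tibble(filter = names(x$removed), removed = as.integer(x$removed))
}

#' Write a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    list(n_samples_in = report$n_samples_in,
         n_samples_out = report$n_samples_out,
         n_snps_in = report$n_snps_in, n_snps_out = report$n_snps_out,
         removed = as.list(report$removed),
         thresholds = as.list(report$thresholds)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Fill in missing genotype calls
#'
#' `expected` replaces each missing call with the SNP's expected dosage
#' 2*p-hat (a real number); `mode` uses the SNP's most frequent observed
#' genotype (smallest dosage on ties). Observed calls are never changed.
#'
#' @param geno A `genotype_matrix`.
#' @param method `"expected"` or `"mode"`.
#' @return A `genotype_matrix` with no missing values.
#' @export
impute_missing <- function(geno, method = c("expected", "mode")) {
  method <- match.arg(method)
  G <- geno$values
  miss <- colSums(is.na(G))
  if (any(miss == nrow(G))) {
    ta_stop("fully missing SNP encountered; run qc_filter first")
  }
  for (j in which(miss > 0)) {
    g <- G[, j]
    fill <- if (method == "expected") {
      mean(g, na.rm = TRUE)
    } else {
      tab <- table(factor(round(g), levels = 0:2))
      as.numeric(names(tab)[which.max(tab)])
    }
    G[is.na(g), j] <- fill
  }
  geno$values <- G
  geno
}
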