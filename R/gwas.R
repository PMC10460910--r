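#' Fit the null linear mixed model (no SNP) by REML
#'
#' One eigendecomposition of the GRM plus a one-dimensional optimization of
#' the variance ratio `delta = sigma2_e / sigma2_g` (EMMA-style). The
#' rotation is cached and reused by [gwas_scan()] and
#' [permutation_threshold()].
#'
#' @param y Numeric phenotype vector (a 0/1 case-control vector is modelled
#'   linearly).
#' @param covariates Optional covariate matrix/data.frame (intercept always
#'   added).
#' @param grm A `rel_matrix`.
#' @return An object of class `null_lmm`: variance components, the cached
#'   eigendecomposition, rotated responses and covariates.
#' @export
fit_null_lmm <- function(y, covariates = NULL, grm) {
  stopifnot(inherits(grm, "rel_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(grm$values)) ta_stop("GRM dimension must match y")
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) ta_stop("covariates are rank deficient")
  eig <- eigen(grm$values, symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-6 * max(abs(d))) {
    ta_stop("GRM is not positive semidefinite")
  }
  d <- pmax(d, 0)
  U <- eig$vectors
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, X)
  fit <- reml_1d(yt, Xt, d)
  structure(c(fit, list(U = U, d = d, yt = yt, Xt = Xt, X = X, y = y,
                        labels = grm$labels)),
            class = "null_lmm")
}

# REML profile over log10(delta); returns variance components
reml_1d <- function(yt, Xt, d, lower = -6, upper = 6) {
  n <- length(yt); p <- ncol(Xt)
  negll <- function(log10d) {
    delta <- 10^log10d
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    0.5 * ((n - p) * log(rss) + sum(log(d + delta)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(negll, c(lower, upper), tol = 1e-8)
  delta <- 10^opt$minimum
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, Xt * w)
  beta <- as.numeric(solve(XtWX, crossprod(Xt, yt * w)))
  r <- yt - Xt %*% beta
  sigma2_g <- sum(w * r^2) / (n - p)
  list(sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g, delta = delta,
       beta_null = beta, weights = w)
}

#' @export
print.null_lmm <- function(x, ...) {
  cat(sprintf("<null_lmm> sigma2_g = %.4g, sigma2_e = %.4g (h2_snp = %.3f)\n",
              x$sigma2_g, x$sigma2_e,
              x$sigma2_g / (x$sigma2_g + x$sigma2_e)))
  invisible(x)
}

#' @export
glance.null_lmm <- function(x, ...) {
  tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e, delta = x$delta,
         h2_snp = x$sigma2_g / (x$sigma2_g + x$sigma2_e))
}

#' Mixed-model single-SNP association scan
#'
#' Per-SNP generalized-least-squares Wald tests in the whitened space of
#' the null fit (variance components estimated once under the null and
#' reused for every SNP); two-sided p-values from the normal approximation.
#' Monomorphic SNPs get effect 0, p = 1 and a flag.
#'
#' @param geno A `genotype_matrix` (no missing values).
#' @param null_fit A `null_lmm` from [fit_null_lmm()] on the same samples.
#' @return A `gwas_result`: tibble with chrom, pos, id, beta, se, wald,
#'   p, monomorphic flag; attributes carry the variance components and
#'   genomic inflation factor.
#' @export
gwas_scan <- function(geno, null_fit) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(null_fit, "null_lmm"))
  G <- geno$values
  if (anyNA(G)) ta_stop("missing genotypes: impute first")
  if (nrow(G) != length(null_fit$y)) ta_stop("sample mismatch with null fit")
  sw <- sqrt(null_fit$weights)
  ys <- sw * null_fit$yt
  Xs <- null_fit$Xt * sw
  Gs <- crossprod(null_fit$U, G) * sw
  XtX_inv <- solve(crossprod(Xs))
  PG <- Gs - Xs %*% (XtX_inv %*% crossprod(Xs, Gs))
  Py <- ys - Xs %*% (XtX_inv %*% crossprod(Xs, ys))
  gPg <- colSums(PG^2)
  gPy <- as.numeric(crossprod(PG, ys))
  mono <- gPg < 1e-12
  beta <- ifelse(mono, 0, gPy / gPg)
  se <- ifelse(mono, NA_real_, sqrt(null_fit$sigma2_g / gPg))
  wald <- ifelse(mono, 0, beta / se)
  p <- ifelse(mono, 1, 2 * pnorm(-abs(wald)))
  res <- bind_cols(
    geno$variants[, c("chrom", "pos", "id")],
    tibble(beta = beta, se = se, wald = wald, p = p, monomorphic = mono)
  )
  attr(res, "sigma2_g") <- null_fit$sigma2_g
  attr(res, "sigma2_e") <- null_fit$sigma2_e
  attr(res, "lambda_gc") <- if (sum(!mono) >= 100) {
    genomic_inflation(p[!mono])
  } else NA_real_
  class(res) <- c("gwas_result", class(res))
  res
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549364`, the observed over
#' expected median one-degree-of-freedom association statistic.
#'
#' @param pvals p-values in (0, 1].
#' @return lambda (scalar).
#' @export
genomic_inflation <- function(pvals) {
  if (length(pvals) < 100) warn("genomic inflation from fewer than 100 p-values")
  if (any(pvals <= 0 | pvals > 1)) ta_stop("p-values must lie in (0, 1]")
  median(qchisq(1 - pvals, df = 1)) / qchisq(0.5, df = 1)
}

#' Bonferroni genome-wide threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  check_fraction(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  m <- check_count(m, "m", min = 1L)
  alpha / m
}

#' Permutation-based genome-wide significance threshold
#'
#' Permutes the phenotype vector (covariates stay attached to the genotype
#' rows), refits the null variance components on the cached GRM rotation,
#' reruns the scan, and records the genome-wide minimum p-value. The
#' threshold is the `quantile`-th empirical quantile (type 7) of that
#' minimum-p distribution.
#'
#' @param geno A `genotype_matrix`.
#' @param y Phenotype vector.
#' @param covariates Optional covariates.
#' @param grm A `rel_matrix`.
#' @param n_perm Number of permutations (default 500).
#' @param quantile_prob Quantile of the min-p distribution (default 0.05).
#' @param seed RNG seed.
#' @return A list of class `perm_threshold`: `threshold`, `min_p` (vector),
#'   `n_perm`, `quantile`, `seed`.
#' @export
permutation_threshold <- function(geno, y, covariates = NULL, grm,
                                  n_perm = 500L, quantile_prob = 0.05,
                                  seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 2L)
  check_fraction(quantile_prob, "quantile_prob", 0, 1,
                 lo_open = TRUE, hi_open = TRUE)
  null0 <- fit_null_lmm(y, covariates, grm)
  sw_cache <- NULL
  set.seed(seed)
  min_p <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    ytp <- as.numeric(crossprod(null0$U, yp))
    fit <- reml_1d(ytp, null0$Xt, null0$d)
    nf <- null0
    nf$yt <- ytp; nf$y <- yp
    nf$sigma2_g <- fit$sigma2_g; nf$sigma2_e <- fit$sigma2_e
    nf$delta <- fit$delta; nf$weights <- fit$weights
    res <- gwas_scan(geno, nf)
    min(res$p)
  }, numeric(1))
  structure(list(
    threshold = as.numeric(quantile(min_p, probs = quantile_prob, type = 7)),
    min_p = min_p, n_perm = n_perm, quantile = quantile_prob, seed = seed
  ), class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("<perm_threshold> %.3g (%d permutations, %g quantile of min p)\n",
              x$threshold, x$n_perm, x$quantile))
  invisible(x)
}

#' Annotate significant SNPs with nearby genes
#'
#' A gene is reported for a SNP when its interval intersects
#' `[pos - flank, pos + flank]` (1-based inclusive coordinates; BED input is
#' converted on read by rtracklayer). Duplicate gene hits are collapsed and
#' the table is sorted by chromosome then position.
#'
#' @param hits Tibble with at least `chrom`, `pos` (and optionally `id`,
#'   `p`).
#' @param annotations A `GRanges` (e.g. from [read_annotations()]) or a
#'   tibble with `chrom`, `start`, `end`, `gene`.
#' @param flank Flanking distance in bp (default 50000).
#' @return Tibble: chrom, pos, id, gene, gene_start, gene_end, distance.
#' @export
annotate_hits <- function(hits, annotations, flank = 50000) {
  ann <- if (inherits(annotations, "GRanges")) {
    tibble(
      chrom = as.character(GenomicRanges::seqnames(annotations)),
      start = GenomicRanges::start(annotations),
      end = GenomicRanges::end(annotations),
      gene = if (!is.null(annotations$name)) as.character(annotations$name)
             else if (!is.null(annotations$gene)) as.character(annotations$gene)
             else as.character(seq_along(annotations))
    )
  } else as_tibble(annotations)
  known <- hits$chrom %in% ann$chrom
  if (any(!known)) {
    warn(sprintf("%d hit(s) on chromosomes absent from the annotation; skipped",
                 sum(!known)))
    hits <- hits[known, , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    return(tibble(chrom = character(), pos = integer(), id = character(),
                  gene = character(), gene_start = integer(),
                  gene_end = integer(), distance = integer()))
  }
  snp_gr <- GenomicRanges::GRanges(
    hits$chrom,
    IRanges::IRanges(pmax(1L, hits$pos - flank), hits$pos + flank)
  )
  ann_gr <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start, ann$end)
  )
  ov <- GenomicRanges::findOverlaps(snp_gr, ann_gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  out <- tibble(
    chrom = hits$chrom[qh], pos = hits$pos[qh],
    id = if (!is.null(hits$id)) hits$id[qh] else NA_character_,
    gene = ann$gene[sh], gene_start = ann$start[sh], gene_end = ann$end[sh],
    distance = pmax(0L, pmax(ann$start[sh] - hits$pos[qh],
                             hits$pos[qh] - ann$end[sh]))
  )
  distinct(arrange(out, .data$chrom, .data$pos, .data$gene))
}

#' Read gene annotations from BED or GFF3
#'
#' @param path Annotation file (`.bed`, `.gff`, `.gff3`).
#' @return A `GRanges` (BED's 0-based half-open intervals are converted to
#'   1-based inclusive on import).
#' @export
read_annotations <- function(path) {
  rtracklayer::import(path)
}

#' Yates-corrected chi-squared test of sex against case status
#'
#' @param sex 0/1 vector.
#' @param phenotype 0/1 vector.
#' @return Tidy tibble with statistic, p.value, df.
#' @export
sex_association_chisq <- function(sex, phenotype) {
  ct <- stats::chisq.test(table(sex, phenotype), correct = TRUE)
  tibble(statistic = unname(ct$statistic), p.value = ct$p.value,
         df = unname(ct$parameter))
}

#' Manhattan or QQ plot of a GWAS scan
#'
#' @param object A `gwas_result`.
#' @param type `"manhattan"` or `"qq"`.
#' @param thresholds Optional numeric p-value thresholds drawn as lines.
#' @param ... Unused.
#' @export
autoplot.gwas_result <- function(object, type = c("manhattan", "qq"),
                                 thresholds = NULL, ...) {
  type <- match.arg(type)
  df <- as_tibble(object)
  if (type == "manhattan") {
    df <- df |>
      group_by(.data$chrom) |>
      mutate(offset = 0) |>
      ungroup()
    chr_len <- df |> group_by(.data$chrom) |>
      summarise(len = max(.data$pos), .groups = "drop") |>
      mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
    df <- left_join(df, chr_len[, c("chrom", "offset")], by = "chrom",
                    suffix = c("", ".chr")) |>
      mutate(x = .data$pos + .data$offset.chr)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x,
                                          y = -log10(.data$p),
                                          colour = .data$chrom)) +
      ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
      ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
      ggplot2::theme_minimal()
    for (th in thresholds) {
      p <- p + ggplot2::geom_hline(yintercept = -log10(th),
                                   linetype = "dashed", colour = "red")
    }
    p
  } else {
    obs <- sort(df$p)
    exp <- stats::ppoints(length(obs))
    qq <- tibble(expected = -log10(exp), observed = -log10(obs))
    ggplot2::ggplot(qq, ggplot2::aes(.data$expected, .data$observed)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
      ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                    y = expression(Observed ~ -log[10](p))) +
      ggplot2::theme_minimal()
  }
}
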