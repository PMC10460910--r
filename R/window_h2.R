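#' Partition the SNP panel into consecutive fixed-size windows
#'
#' Per chromosome, consecutive blocks of `window_snps` SNPs. A trailing
#' remainder keeps its own window when it has at least `window_snps / 2`
#' SNPs and is otherwise merged into the previous window. A chromosome with
#' fewer than `window_snps / 2` SNPs becomes a single window with a
#' warning.
#'
#' @param variants Variant tibble (`chrom`, `pos`), sorted by chromosome
#'   and position.
#' @param window_snps Window size in SNPs (default 90).
#' @return Tibble of class `window_spec`: window, chrom, first, last
#'   (SNP indices into the variant table), n_snps, span_bp.
#' @export
make_windows <- function(variants, window_snps = 90L) {
  window_snps <- check_count(window_snps, "window_snps", min = 2L)
  out <- list()
  wid <- 0L
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    m <- length(idx)
    if (m < window_snps / 2) {
      warn(sprintf("chromosome %s has only %d SNPs; single window", ch, m))
      starts <- 1L; ends <- m
    } else {
      n_full <- m %/% window_snps
      rem <- m %% window_snps
      starts <- seq(1L, by = window_snps, length.out = n_full)
      ends <- starts + window_snps - 1L
      if (rem >= window_snps / 2) {
        starts <- c(starts, n_full * window_snps + 1L)
        ends <- c(ends, m)
      } else if (rem > 0L) {
        if (n_full == 0L) { starts <- 1L; ends <- m }
        else ends[n_full] <- m            # merge remainder into last window
      }
    }
    for (k in seq_along(starts)) {
      wid <- wid + 1L
      first <- idx[starts[k]]; last <- idx[ends[k]]
      out[[wid]] <- tibble(
        window = wid, chrom = ch, first = first, last = last,
        n_snps = last - first + 1L,
        span_bp = variants$pos[last] - variants$pos[first]
      )
    }
  }
  res <- bind_rows(out)
  class(res) <- c("window_spec", class(res))
  res
}

# REML log-likelihood for variance components over a list of covariance
# structures (last one implicitly the identity); direct dense evaluation
reml_loglik_vc <- function(theta, y, X, Ks) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Ks)) V <- V + theta[i] * Ks[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  Py <- Vi_y - Vi_X %*% beta
  0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
           sum(y * Py))
}

#' Two-variance-component REML fit for one window
#'
#' Restricted maximum likelihood for
#' `y = X beta + g_w + g_r + e` with `g_w ~ N(0, G_w s2_w)`,
#' `g_r ~ N(0, G_r s2_r)`, `e ~ N(0, I s2_e)`, maximized directly over the
#' nonnegative component scale by box-constrained quasi-Newton iterations
#' (relative log-likelihood tolerance 1e-6, at most 200 evaluations per
#' restart). The binary phenotype is modelled linearly.
#'
#' @param y Phenotype vector.
#' @param covariates Optional covariates (intercept added).
#' @param G_w,G_r `rel_matrix` objects (window and rest-of-genome GRMs).
#' @return Tibble row: sigma2_w, sigma2_r, sigma2_e, h2_local, converged.
#' @export
fit_two_grm_reml <- function(y, covariates = NULL, G_w, G_r) {
  stopifnot(inherits(G_w, "rel_matrix"), inherits(G_r, "rel_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  X <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  vy <- var(y)
  Ks <- list(G_w$values, G_r$values)
  obj <- function(th) reml_loglik_vc(th, y, X, Ks)
  fit <- stats::optim(c(vy / 4, vy / 4, vy / 2), obj, method = "L-BFGS-B",
                      lower = rep(1e-8 * vy, 3),
                      control = list(maxit = 200, factr = 1e7))
  th <- fit$par
  tibble(sigma2_w = th[1], sigma2_r = th[2], sigma2_e = th[3],
         h2_local = th[1] / sum(th),
         converged = fit$convergence == 0)
}

#' Regional heritability scan over all windows
#'
#' For every window, the window GRM is built from the window's SNPs only
#' and the rest-of-genome GRM is obtained by downdating the whole-genome
#' cross-product (subtracting the window's contribution and rescaling the
#' denominator). Windows are ranked by local heritability (descending,
#' ties by window id) and the top `floor(top_fraction * n_windows)` are
#' flagged.
#'
#' @param geno A `genotype_matrix` (no missing values).
#' @param y Phenotype vector.
#' @param covariates Optional covariates.
#' @param windows A `window_spec` from [make_windows()].
#' @param top_fraction Fraction of windows to flag (default 0.05).
#' @return A `window_scan` tibble: window spec columns + variance
#'   components, h2_local, rank, top flag.
#' @export
scan_windows <- function(geno, y, covariates = NULL, windows,
                         top_fraction = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  check_fraction(top_fraction, "top_fraction", 0, 1, lo_open = TRUE)
  G <- geno$values
  if (anyNA(G)) ta_stop("missing genotypes: impute first")
  p_all <- colMeans(G) / 2
  Xc <- sweep(G, 2, 2 * p_all)
  S_all <- tcrossprod(Xc)
  denom_all <- 2 * sum(p_all * (1 - p_all))
  fits <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    cols <- windows$first[k]:windows$last[k]
    Xw <- Xc[, cols, drop = FALSE]
    S_w <- tcrossprod(Xw)
    denom_w <- 2 * sum(p_all[cols] * (1 - p_all[cols]))
    denom_r <- denom_all - denom_w
    if (denom_w <= 0 || denom_r <= 0) {
      fits[[k]] <- tibble(sigma2_w = NA_real_, sigma2_r = NA_real_,
                          sigma2_e = NA_real_, h2_local = NA_real_,
                          converged = FALSE)
      next
    }
    G_w <- rel_matrix(S_w / denom_w, geno$samples$id, "GRM")
    G_r <- rel_matrix((S_all - S_w) / denom_r, geno$samples$id, "GRM")
    fits[[k]] <- fit_two_grm_reml(y, covariates, G_w, G_r)
  }
  res <- bind_cols(as_tibble(windows), bind_rows(fits))
  ord <- order(-res$h2_local, res$window)
  res$rank <- NA_integer_
  res$rank[ord] <- seq_len(nrow(res))
  n_top <- floor(top_fraction * nrow(res))
  res$top <- res$rank <= n_top
  class(res) <- c("window_scan", class(res))
  res
}

#' Plot local heritability along the genome
#'
#' @param object A `window_scan`.
#' @param ... Unused.
#' @export
autoplot.window_scan <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$first + df$last) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$h2_local,
                                   colour = .data$top)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "SNP index (window midpoint)",
                  y = "local heritability") +
    ggplot2::theme_minimal()
}
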