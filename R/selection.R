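#' Per-site nucleotide diversity
#'
#' Pairwise-difference definition at a biallelic site:
#' `pi = 2 a b / (n (n - 1))` with `a`, `b` the two allele counts among `n`
#' haplotypes. Monomorphic sites score 0.
#'
#' @param haps A `haplotype_set`.
#' @return Numeric vector, one value per site.
#' @export
site_pi <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  n <- nrow(haps$matrix)
  if (n < 2) ta_stop("need at least two haplotypes")
  a <- colSums(haps$matrix)
  2 * a * (n - a) / (n * (n - 1))
}

# shared windowing along physical positions
bp_windows <- function(positions, chromosome, window_bp) {
  win <- integer(length(positions))
  off <- 0L
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    w <- (positions[idx] - min(positions[idx])) %/% window_bp
    win[idx] <- off + as.integer(w) + 1L
    off <- max(win[idx])
  }
  win
}

#' Windowed difference in nucleotide diversity between groups
#'
#' `delta_pi = mean window pi(control) - mean window pi(case)`: reduced
#' diversity in the selected (case) group scores positive. Swapping the
#' group arguments flips the sign.
#'
#' @param case_haps,control_haps `haplotype_set`s sharing one site map.
#' @param window_bp Window width in bp (default 100000).
#' @return Tibble: window, chrom, start, end, n_sites, pi_case, pi_control,
#'   delta_pi.
#' @export
delta_pi <- function(case_haps, control_haps, window_bp = 1e5) {
  stopifnot(identical(case_haps$positions, control_haps$positions))
  pc <- site_pi(case_haps)
  pk <- site_pi(control_haps)
  win <- bp_windows(case_haps$positions, case_haps$chromosome, window_bp)
  tibble(window = win, chrom = case_haps$chromosome,
         pos = case_haps$positions, pi_case = pc, pi_control = pk) |>
    group_by(.data$window, .data$chrom) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_sites = n(),
              pi_case = mean(.data$pi_case),
              pi_control = mean(.data$pi_control), .groups = "drop") |>
    mutate(delta_pi = .data$pi_control - .data$pi_case) |>
    arrange(.data$window)
}

# walk outward from the core over the carrier haplotypes, tracking the
# partition into distinct extended haplotypes; returns EHH at each visited
# column (including the core, EHH = 1)
ehh_walk <- function(H, carriers, cols) {
  n <- length(carriers)
  denom <- n * (n - 1) / 2
  g <- rep(1L, n)
  ehh <- numeric(length(cols))
  ehh[1] <- 1
  for (k in seq_along(cols)[-1]) {
    key <- g * 2L + H[carriers, cols[k]]
    g <- match(key, unique(key))
    sz <- tabulate(g)
    ehh[k] <- sum(sz * (sz - 1) / 2) / denom
  }
  ehh
}

#' Extended haplotype homozygosity outward from a core site
#'
#' `EHH(x)` is the probability that two randomly drawn carriers of the core
#' allele are identical over every site between the core and `x`;
#' `EHH(core) = 1` and EHH is nonincreasing outward.
#'
#' @param haps A `haplotype_set`.
#' @param core_index Column index of the core site.
#' @param core_allele 0 or 1.
#' @return Numeric vector over the core chromosome's sites (named by column
#'   index); `NA` for sites on other chromosomes.
#' @export
ehh <- function(haps, core_index, core_allele) {
  H <- haps$matrix
  carriers <- which(H[, core_index] == core_allele)
  if (length(carriers) < 2) {
    ta_stop("core allele carried by fewer than two haplotypes")
  }
  chrom <- haps$chromosome[core_index]
  on_chr <- which(haps$chromosome == chrom)
  out <- rep(NA_real_, ncol(H))
  right <- on_chr[on_chr >= core_index]
  left <- rev(on_chr[on_chr <= core_index])
  out[right] <- ehh_walk(H, carriers, right)
  out[left] <- ehh_walk(H, carriers, left)
  out[core_index] <- 1
  out[on_chr]
}

# integrate EHH outward (trapezoid over `dist`) until below cutoff;
# returns NA when the chromosome end arrives first (truncated)
ihh_one_side <- function(H, carriers, cols, dist, cutoff) {
  e <- ehh_walk(H, carriers, cols)
  total <- 0
  for (k in seq_along(cols)[-1]) {
    step <- abs(dist[k] - dist[k - 1])
    total <- total + 0.5 * (e[k] + e[k - 1]) * step
    if (e[k] < cutoff) return(total)
  }
  if (length(cols) == 1L || e[length(cols)] < cutoff) total else NA_real_
}

unstandardized_hh_scores <- function(haps, maf_min, ehh_cutoff,
                                     use_positions, keep_truncated) {
  H <- haps$matrix
  m <- ncol(H)
  freq <- colMeans(H)
  score <- rep(NA_real_, m)
  for (ch in unique(haps$chromosome)) {
    on_chr <- which(haps$chromosome == ch)
    for (j in on_chr) {
      p <- freq[j]
      if (min(p, 1 - p) < maf_min) next
      dist_all <- if (use_positions) haps$positions else seq_len(m)
      right <- on_chr[on_chr >= j]
      left <- rev(on_chr[on_chr <= j])
      ihh_allele <- function(al) {
        carriers <- which(H[, j] == al)
        if (length(carriers) < 2) return(NA_real_)
        r <- ihh_one_side(H, carriers, right, dist_all[right], ehh_cutoff)
        l <- ihh_one_side(H, carriers, left, dist_all[left], ehh_cutoff)
        if ((is.na(r) || is.na(l)) && !keep_truncated) return(NA_real_)
        sum(c(r, l), na.rm = TRUE)
      }
      ihh_d <- ihh_allele(1L)   # derived = alt allele
      ihh_a <- ihh_allele(0L)
      if (is.na(ihh_d) || is.na(ihh_a) || ihh_d <= 0 || ihh_a <= 0) next
      score[j] <- log(ihh_a / ihh_d)
    }
  }
  score
}

standardize_by_freq_bin <- function(score, freq, n_bins) {
  out <- rep(NA_real_, length(score))
  bins <- cut(freq, breaks = seq(0, 1, length.out = n_bins + 1),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- which(bins == b & !is.na(score))
    if (length(idx) < 2) next
    s <- score[idx]
    if (sd(s) == 0) next
    out[idx] <- (s - mean(s)) / sd(s)
  }
  out
}

#' Integrated haplotype score (iHS)
#'
#' Per site, the log-ratio of the ancestral to derived integrated EHH
#' (trapezoid integral over physical distance until EHH falls below
#' `ehh_cutoff`), standardized to mean 0 / SD 1 within derived-allele
#' frequency bins. The derived allele is the alt (1) allele. Sites whose
#' EHH never reaches the cutoff before the chromosome end are dropped
#' unless `keep_truncated = TRUE`.
#'
#' @param haps A `haplotype_set`.
#' @param maf_min Minimum minor allele frequency at the core.
#' @param ehh_cutoff EHH truncation level (default 0.05).
#' @param n_bins Number of derived-allele-frequency bins (default 20).
#' @param keep_truncated Keep chromosome-end-truncated integrals.
#' @return Tibble: chrom, pos, freq_derived, ihs_unstd, ihs.
#' @export
ihs <- function(haps, maf_min = 0.05, ehh_cutoff = 0.05, n_bins = 20L,
                keep_truncated = FALSE) {
  raw <- unstandardized_hh_scores(haps, maf_min, ehh_cutoff,
                                  use_positions = TRUE,
                                  keep_truncated = keep_truncated)
  freq <- colMeans(haps$matrix)
  tibble(chrom = haps$chromosome, pos = haps$positions,
         freq_derived = freq, ihs_unstd = raw,
         ihs = standardize_by_freq_bin(raw, freq, n_bins))
}

#' Number of segregating sites by length (nSL)
#'
#' Identical construction to [ihs()] but haplotype length is measured in
#' segregating-site counts rather than physical distance, making the score
#' invariant to the physical map.
#'
#' @inheritParams ihs
#' @return Tibble: chrom, pos, freq_derived, nsl_unstd, nsl.
#' @export
nsl <- function(haps, maf_min = 0.05, n_bins = 20L, ehh_cutoff = 0.05,
                keep_truncated = FALSE) {
  raw <- unstandardized_hh_scores(haps, maf_min, ehh_cutoff,
                                  use_positions = FALSE,
                                  keep_truncated = keep_truncated)
  freq <- colMeans(haps$matrix)
  tibble(chrom = haps$chromosome, pos = haps$positions,
         freq_derived = freq, nsl_unstd = raw,
         nsl = standardize_by_freq_bin(raw, freq, n_bins))
}

#' Haplotype homozygosity H12 in SNP windows
#'
#' With window haplotype frequencies `p1 >= p2 >= ...`,
#' `H12 = (p1 + p2)^2 + sum_{i >= 3} p_i^2`; sensitive to both hard and
#' soft sweeps.
#'
#' @param haps A `haplotype_set`.
#' @param window_snps Window width in SNPs (default 20).
#' @return Tibble: window, chrom, first, last, start, end, h12.
#' @export
h12 <- function(haps, window_snps = 20L) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (nrow(haps$matrix) < 2) ta_stop("need at least two haplotypes")
  window_snps <- check_count(window_snps, "window_snps", min = 1L)
  out <- list(); wid <- 0L
  for (ch in unique(haps$chromosome)) {
    idx <- which(haps$chromosome == ch)
    starts <- seq(1L, length(idx), by = window_snps)
    for (s in starts) {
      cols <- idx[s:min(s + window_snps - 1L, length(idx))]
      key <- apply(haps$matrix[, cols, drop = FALSE], 1, paste, collapse = "")
      p <- sort(as.numeric(table(key)) / length(key), decreasing = TRUE)
      val <- if (length(p) == 1L) 1 else (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
      wid <- wid + 1L
      out[[wid]] <- tibble(window = wid, chrom = ch,
                           first = cols[1], last = cols[length(cols)],
                           start = haps$positions[cols[1]],
                           end = haps$positions[cols[length(cols)]],
                           h12 = val)
    }
  }
  bind_rows(out)
}

#' Fractional-rank p-values for a selection statistic
#'
#' Right tail: `p_i = 1 - rank_i / (n + 1)` with average ranks for ties, so
#' every p lies strictly inside (0, 1). The left tail negates the values
#' first; `two_sided` ranks absolute values.
#'
#' @param stat Numeric vector (NAs propagate).
#' @param tail `"right"`, `"left"` or `"two_sided"`.
#' @return Numeric p-value vector.
#' @export
fractional_rank_pvalues <- function(stat, tail = c("right", "left",
                                                   "two_sided")) {
  tail <- match.arg(tail)
  x <- switch(tail, right = stat, left = -stat, two_sided = abs(stat))
  ok <- !is.na(x)
  if (sum(ok) < 2) ta_stop("need at least two finite values")
  p <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  p[ok] <- 1 - r / (sum(ok) + 1)
  p
}

#' Robust (MCD) correlation matrix between selection statistics
#'
#' Minimum-covariance-determinant location/scatter on the complete rows,
#' converted to a correlation matrix. Subset search uses `nsamp` random
#' subsets under a fixed seed, so the estimate is deterministic.
#'
#' @param stat_matrix Numeric matrix/data frame, one column per statistic.
#' @param support_fraction Fraction of rows the MCD covers (default 0.75).
#' @param nsamp Number of subsets searched (default 500).
#' @param seed RNG seed.
#' @return s x s correlation matrix with unit diagonal.
#' @export
robust_correlation <- function(stat_matrix, support_fraction = 0.75,
                               nsamp = 500L, seed = 1L) {
  X <- as.matrix(stat_matrix)
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) <= ncol(X)) ta_stop("need more complete rows than statistics")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    ta_stop(sprintf("constant statistic column: %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  set.seed(seed)
  rob <- tryCatch(
    MASS::cov.rob(X, method = "mcd", nsamp = nsamp,
                  quantile.used = floor(support_fraction * nrow(X))),
    error = function(e) {
      # exactly collinear statistics make the MCD scatter singular;
      # fall back to the classical estimate for this degenerate case
      warn(sprintf("MCD scatter is singular (%s); using classical covariance",
                   conditionMessage(e)))
      list(cov = stats::cov(X))
    })
  R <- stats::cov2cor(rob$cov)
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}

#' Decorrelated composite of multiple signals (DCMS)
#'
#' `DCMS_j = sum_i log((1 - p_ij) / p_ij) / sum_k |r_ik|`: each
#' statistic's log-odds score is down-weighted by its total absolute
#' correlation (including the unit self-correlation) with all statistics.
#' Sites with any missing component p-value get a missing DCMS.
#'
#' @param p_matrix Sites x statistics matrix of p-values strictly in (0,1).
#' @param correlation s x s correlation matrix (e.g. from
#'   [robust_correlation()]).
#' @return Numeric DCMS vector, one value per site.
#' @export
dcms <- function(p_matrix, correlation) {
  P <- as.matrix(p_matrix)
  s <- ncol(P)
  stopifnot(nrow(correlation) == s, ncol(correlation) == s)
  finite <- P[!is.na(P)]
  if (length(finite) && (min(finite) <= 0 || max(finite) >= 1)) {
    ta_stop("p-values must lie strictly inside (0, 1)")
  }
  w <- 1 / rowSums(abs(correlation))
  as.numeric(log((1 - P) / P) %*% w)
}

#' Upper-tail p-values for DCMS values from a robust normal fit
#'
#' Location and scale come from a Huber M-estimated intercept-only linear
#' model (tuning constant 1.345, MAD-initialized scale); the p-value is the
#' upper normal tail at the standardized DCMS value.
#'
#' @param dcms_values Numeric vector (>= 30 finite values).
#' @return List of class `dcms_fit`: `p` (vector), `location`, `scale`.
#' @export
dcms_pvalues <- function(dcms_values) {
  ok <- is.finite(dcms_values)
  if (sum(ok) < 30) ta_stop("need at least 30 finite DCMS values")
  fit <- MASS::rlm(dcms_values[ok] ~ 1, psi = MASS::psi.huber, k = 1.345,
                   maxit = 100)
  location <- unname(stats::coef(fit)[1])
  scale <- fit$s
  if (!is.finite(scale) || scale <= 0) ta_stop("robust scale is zero")
  p <- rep(NA_real_, length(dcms_values))
  p[ok] <- pnorm(dcms_values[ok], mean = location, sd = scale,
                 lower.tail = FALSE)
  structure(list(p = p, location = location, scale = scale),
            class = "dcms_fit")
}

#' Composite selection-signature scan for case and control groups
#'
#' Runs the full pipeline per group: per-site and windowed raw statistics
#' (pi, delta-pi against the other group, |nSL|, H12, |iHS|), fractional-rank
#' p-values, MCD-robust correlation between statistics, per-site DCMS, and
#' robust-normal DCMS p-values. Window statistics are joined per site by
#' assigning each site its containing window's value. Candidate sites fall
#' at DCMS p <= `cutoff`; with annotations, case-specific genes are those
#' near case candidates and absent from the control candidate list.
#'
#' @param case_haps,control_haps `haplotype_set`s sharing one site map.
#' @param statistics Character subset of
#'   `c("pi", "delta_pi", "nsl", "h12", "ihs")`.
#' @param pi_window_bp Window (bp) for the diversity statistics.
#' @param h12_window_snps Window (SNPs) for H12.
#' @param maf_min,ehh_cutoff,n_bins Passed to [ihs()] / [nsl()].
#' @param cutoff DCMS p-value cutoff for candidate sites (default 1e-4).
#' @param annotations Optional gene intervals for [annotate_hits()].
#' @param flank Gene flank in bp (default 50000).
#' @param seed Seed for the MCD subset search.
#' @param tails Named list overriding the per-statistic tail convention
#'   (defaults: pi left, all others right).
#' @return List of class `selection_scan`: `case`, `control` (per-site
#'   tibbles with raw statistics, DCMS and p), `candidates` (per group),
#'   `case_specific_genes`, `correlations`.
#' @export
selection_scan <- function(case_haps, control_haps,
                           statistics = c("pi", "delta_pi", "nsl", "h12",
                                          "ihs"),
                           pi_window_bp = 1e5, h12_window_snps = 20L,
                           maf_min = 0.05, ehh_cutoff = 0.05, n_bins = 20L,
                           cutoff = 1e-4, annotations = NULL, flank = 50000,
                           seed = 1L, tails = list()) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  stopifnot(identical(case_haps$positions, control_haps$positions))
  default_tails <- list(pi = "left", delta_pi = "right", nsl = "right",
                        h12 = "right", ihs = "right")
  tails <- utils::modifyList(default_tails, tails)

  group_table <- function(focal, other) {
    pos <- focal$positions
    tab <- tibble(chrom = focal$chromosome, pos = pos)
    win_bp <- bp_windows(pos, focal$chromosome, pi_window_bp)
    if ("pi" %in% statistics) {
      pw <- tibble(win = win_bp, pi = site_pi(focal)) |>
        group_by(.data$win) |> summarise(v = mean(.data$pi))
      tab$pi <- pw$v[match(win_bp, pw$win)]
    }
    if ("delta_pi" %in% statistics) {
      dp <- delta_pi(other, focal, window_bp = pi_window_bp)
      # delta_pi(other, focal): focal is the "control" argument, so
      # pi(focal) - pi(other); flip so reduced focal diversity is positive
      tab$delta_pi <- -dp$delta_pi[match(win_bp, dp$window)]
    }
    if ("nsl" %in% statistics) {
      tab$nsl <- abs(nsl(focal, maf_min = maf_min, n_bins = n_bins,
                         ehh_cutoff = ehh_cutoff)$nsl)
    }
    if ("h12" %in% statistics) {
      hw <- h12(focal, window_snps = h12_window_snps)
      site_win <- findInterval(seq_along(pos),
                               vapply(split(hw$first, hw$window), min,
                                      numeric(1)))
      tab$h12 <- hw$h12[site_win]
    }
    if ("ihs" %in% statistics) {
      tab$ihs <- abs(ihs(focal, maf_min = maf_min, ehh_cutoff = ehh_cutoff,
                         n_bins = n_bins)$ihs)
    }
    stat_cols <- intersect(statistics, names(tab))
    constant <- vapply(stat_cols, function(sc) {
      v <- tab[[sc]]
      stats::sd(v[is.finite(v)]) == 0
    }, logical(1))
    if (any(constant)) {
      warn(sprintf("dropping constant statistic(s): %s",
                   paste(stat_cols[constant], collapse = ", ")))
      stat_cols <- stat_cols[!constant]
    }
    if (length(stat_cols) < 1) ta_stop("no informative statistics left")
    P <- vapply(stat_cols, function(sc) {
      fractional_rank_pvalues(tab[[sc]], tail = tails[[sc]])
    }, numeric(nrow(tab)))
    colnames(P) <- stat_cols
    S <- as.matrix(tab[, stat_cols])
    R <- robust_correlation(S, seed = seed)
    tab$dcms <- dcms(P, R)
    fitp <- dcms_pvalues(tab$dcms)
    tab$dcms_p <- fitp$p
    list(tab = tab, R = R,
         fit = c(location = fitp$location, scale = fitp$scale))
  }

  case_res <- group_table(case_haps, control_haps)
  ctrl_res <- group_table(control_haps, case_haps)
  cands <- function(tab) filter(tab, !is.na(.data$dcms_p),
                                .data$dcms_p <= cutoff)
  case_cand <- cands(case_res$tab)
  ctrl_cand <- cands(ctrl_res$tab)
  case_specific <- NULL
  if (!is.null(annotations)) {
    cg <- annotate_hits(case_cand, annotations, flank = flank)
    kg <- annotate_hits(ctrl_cand, annotations, flank = flank)
    case_specific <- setdiff(unique(cg$gene), unique(kg$gene))
  }
  structure(list(
    case = case_res$tab, control = ctrl_res$tab,
    candidates = list(case = case_cand, control = ctrl_cand),
    case_specific_genes = case_specific,
    correlations = list(case = case_res$R, control = ctrl_res$R),
    cutoff = cutoff
  ), class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat(sprintf("<selection_scan> %d sites; candidates: %d case, %d control (p <= %g)\n",
              nrow(x$case), nrow(x$candidates$case),
              nrow(x$candidates$control), x$cutoff))
  invisible(x)
}

#' Mirrored DCMS plot for case and control groups
#'
#' @param object A `selection_scan`.
#' @param ... Unused.
#' @export
autoplot.selection_scan <- function(object, ...) {
  df <- bind_rows(
    mutate(object$case, group = "case",
           y = -log10(.data$dcms_p)),
    mutate(object$control, group = "control",
           y = log10(.data$dcms_p))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(object$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = expression(sign %*% -log[10](p[DCMS]))) +
    ggplot2::theme_minimal()
}
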