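#' Relationship matrix container
#'
#' @param values n x n symmetric numeric matrix.
#' @param labels Sample/individual ids (row and column names).
#' @param kind `"GRM"` (marker-based) or `"NRM"` (pedigree-based).
#' @return An object of class `rel_matrix`.
#' @export
rel_matrix <- function(values, labels, kind = c("GRM", "NRM")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) ta_stop("relationship matrix not square")
  if (max(abs(values - t(values))) > 1e-8) {
    ta_stop("relationship matrix not symmetric")
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, kind = kind),
            class = "rel_matrix")
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("<rel_matrix> %s, %d individuals\n", x$kind, nrow(x$values)))
  invisible(x)
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = X X' / (2 * sum p_i (1 - p_i))` where X holds genotypes centred by
#' twice the sample frequency of the counted allele. The formula is
#' invariant to which allele is counted, so the counted-allele (alt)
#' frequency is used for determinism; real-valued imputed dosages are
#' accepted.
#'
#' @param geno A `genotype_matrix` with no missing values.
#' @return A `rel_matrix` of kind `"GRM"`.
#' @export
grm_vanraden <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  G <- geno$values
  if (anyNA(G)) ta_stop("missing genotypes: impute or filter first")
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) ta_stop("no polymorphic SNPs: GRM denominator is zero")
  X <- sweep(G[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  rel_matrix(tcrossprod(X) / denom,
             labels = geno$samples$id, kind = "GRM")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Additive relationships from the recursive tabular rules: founders have
#' diagonal 1; `a(i,j) = (a(j,sire_i) + a(j,dam_i)) / 2` for j preceding i;
#' diagonal `1 + a(sire_i, dam_i) / 2`. The pedigree is sorted internally so
#' parents precede offspring; a pedigree cycle raises an error.
#'
#' @param ped A `pedigree` tibble (id, sire, dam; `NA` = unknown).
#' @return A `rel_matrix` of kind `"NRM"`.
#' @export
nrm_tabular <- function(ped) {
  n <- nrow(ped)
  idx <- function(p) match(p, ped$id)
  si <- idx(ped$sire); di <- idx(ped$dam)
  # topological sort: repeatedly emit individuals whose parents are placed
  placed <- logical(n); order_out <- integer(n); k <- 0L
  parent_placed <- function(v) {
    out <- rep(TRUE, n)
    has <- !is.na(v)
    out[has] <- placed[v[has]]
    out
  }
  while (k < n) {
    ready <- !placed & parent_placed(si) & parent_placed(di)
    if (!any(ready)) {
      ta_stop("pedigree contains a cycle (individual its own ancestor)")
    }
    new_idx <- which(ready)
    order_out[k + seq_along(new_idx)] <- new_idx
    placed[new_idx] <- TRUE
    k <- k + length(new_idx)
  }
  A <- matrix(0, n, n)
  for (pos in seq_len(n)) {
    i <- order_out[pos]
    s <- si[i]; d <- di[i]
    if ((!is.na(s) && s == i) || (!is.na(d) && d == i)) {
      ta_stop("pedigree contains a cycle (individual its own parent)")
    }
    if (pos > 1L) {
      prev <- order_out[seq_len(pos - 1L)]
      aij <- numeric(length(prev))
      if (!is.na(s)) aij <- aij + A[prev, s] / 2
      if (!is.na(d)) aij <- aij + A[prev, d] / 2
      A[i, prev] <- aij
      A[prev, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  rel_matrix(A, labels = as.character(ped$id), kind = "NRM")
}

#' Inbreeding coefficients from an NRM
#'
#' `F_j = A_jj - 1`, the diagonal of the numerator relationship matrix
#' minus one; founders have F = 0.
#'
#' @param nrm A `rel_matrix` of kind `"NRM"`.
#' @return A tibble with `id` and `F`.
#' @export
inbreeding_coefficients <- function(nrm) {
  stopifnot(inherits(nrm, "rel_matrix"), nrm$kind == "NRM")
  tibble(id = nrm$labels, F = unname(diag(nrm$values)) - 1)
}

#' Principal components from a relationship matrix
#'
#' Eigendecomposition of the (symmetric) GRM; scores are eigenvectors
#' scaled by the square root of their eigenvalues, and variance fractions
#' are eigenvalues over their total (negative eigenvalues clipped to zero,
#' with a count of clips recorded).
#'
#' @param grm A `rel_matrix`.
#' @param k Number of components to return (default 10 or n).
#' @return A list of class `pca_result` with `scores` (tibble: id, PC1..),
#'   `variance_fraction`, `eigenvalues`, `n_clipped`.
#' @export
pca_from_grm <- function(grm, k = NULL) {
  stopifnot(inherits(grm, "rel_matrix"))
  if (any(!is.finite(grm$values))) ta_stop("non-finite relationship entries")
  n <- nrow(grm$values)
  k <- min(k %||% 10L, n)
  eig <- eigen(grm$values, symmetric = TRUE)
  lam <- eig$values
  n_clipped <- sum(lam < 0)
  lam[lam < 0] <- 0
  total <- sum(lam)
  if (total <= 0) ta_stop("relationship matrix has no positive eigenvalue")
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = bind_cols(tibble(id = grm$labels), as_tibble(scores)),
    variance_fraction = lam / total,
    eigenvalues = lam, n_clipped = n_clipped
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; PC1 explains %.1f%%\n",
              ncol(x$scores) - 1L, 100 * x$variance_fraction[1]))
  invisible(x)
}

#' Scatter plot of the first two principal components
#'
#' @param object A `pca_result`.
#' @param colour Optional vector (e.g. case/control labels) to colour by.
#' @param ... Unused.
#' @export
autoplot.pca_result <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$group <- factor(colour)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Write / read a relationship matrix as labelled TSV
#'
#' @param rel A `rel_matrix`.
#' @param path Output file.
#' @export
write_rel_matrix <- function(rel, path) {
  stopifnot(inherits(rel, "rel_matrix"))
  df <- data.frame(id = rel$labels, rel$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rel_matrix
#' @param kind Matrix kind for the reconstructed object.
#' @export
read_rel_matrix <- function(path, kind = "GRM") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  rel_matrix(as.matrix(df[, -1]), labels = as.character(df$id), kind = kind)
}
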