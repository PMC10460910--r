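# shared fixture builders; everything is generated in code under fixed seeds

small_cohort <- function(n = 100, m = 400, chromosomes = 2, seed = 3,
                         h2 = 0.5, n_qtl = 10, ld_rho = 0.9, sweep = NULL,
                         prevalence = 0.44, sex_effect = 0) {
  cfg <- sim_config(n_individuals = n, n_snps = m,
                    n_chromosomes = chromosomes, ld_rho = ld_rho,
                    h2_liability = h2, prevalence = prevalence,
                    n_qtl = n_qtl, sex_effect = sex_effect,
                    sweep = sweep, seed = seed)
  simulate_cohort(cfg)
}

# genotype matrix from an explicit dosage matrix, one chromosome
toy_geno <- function(values, pos = NULL) {
  values <- as.matrix(values)
  m <- ncol(values)
  genotype_matrix(
    values,
    tibble::tibble(chrom = "chr1",
                   pos = pos %||% seq(1000L, by = 1000L, length.out = m),
                   id = paste0("s", seq_len(m)), ref = "A", alt = "B"),
    tibble::tibble(id = paste0("i", seq_len(nrow(values))))
  )
}

# haplotype set from an explicit binary matrix
toy_haps <- function(H, pos = NULL, chrom = NULL) {
  H <- as.matrix(H)
  structure(list(matrix = H,
                 positions = pos %||% seq(1000L, by = 1000L,
                                          length.out = ncol(H)),
                 chromosome = chrom %||% rep("chr1", ncol(H)),
                 freq = colMeans(H), group = "test"),
            class = "haplotype_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
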