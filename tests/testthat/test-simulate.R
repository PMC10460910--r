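test_that("pedigrees have parents before offspring and honour size caps", {
  ped <- simulate_pedigree(2, n_generations = 1, offspring_per_mating = 1,
                           seed = 1)
  expect_equal(nrow(ped), 3L)
  expect_true(all(is.na(ped$sire[1:2])))
  expect_setequal(c(ped$sire[3], ped$dam[3]), c(1L, 2L))

  ped2a <- simulate_pedigree(10, 3, 2, seed = 1)
  ped2b <- simulate_pedigree(10, 3, 2, seed = 1)
  expect_identical(ped2a, ped2b)

  # emulates the study pedigree's shape: 688 founders, ~1,947 in total
  big <- simulate_pedigree(688, n_generations = 4, offspring_per_mating = 2,
                           seed = 7, max_total = 1947)
  expect_equal(nrow(big), 1947L)
  expect_equal(sum(!is.na(big$sire)), 1259L)
  # every parent precedes its offspring
  pos <- match(big$id, big$id)
  expect_true(all(is.na(big$sire) | match(big$sire, big$id) < pos))
})

test_that("Markov haplotypes reproduce the requested LD level", {
  cfg0 <- sim_config(n_individuals = 200, n_snps = 200, n_chromosomes = 1,
                     ld_rho = 0, seed = 5)
  h0 <- simulate_haplotypes(cfg0)
  r0 <- sapply(seq_len(199), function(j) {
    suppressWarnings(cor(h0$matrix[, j], h0$matrix[, j + 1]))
  })
  expect_lt(abs(mean(r0, na.rm = TRUE)), 0.05)

  cfg <- sim_config(n_individuals = 500, n_snps = 1000, n_chromosomes = 1,
                    ld_rho = 0.95, seed = 7)
  h1 <- simulate_haplotypes(cfg)
  r1 <- sapply(seq_len(999), function(j) {
    suppressWarnings(cor(h1$matrix[, j], h1$matrix[, j + 1]))
  })
  expect_gt(mean(r1, na.rm = TRUE), 0.90)
  expect_lt(mean(r1, na.rm = TRUE), 0.99)

  h2run <- simulate_haplotypes(cfg)
  expect_identical(h1$matrix, h2run$matrix)
  expect_identical(h1$positions, h2run$positions)
})

test_that("genotypes are exactly the haplotype row-pair sums", {
  co <- small_cohort(n = 50, m = 100, seed = 11)
  H <- co$haplotypes$matrix
  G <- H[seq(1, 99, 2), ] + H[seq(2, 100, 2), ]
  expect_equal(unname(co$genotypes$values), unname(G))
})

test_that("liability phenotypes respect the threshold model", {
  co0 <- small_cohort(n = 200, m = 100, h2 = 0, n_qtl = 0, seed = 13)
  expect_true(all(co0$phenotypes$genetic_value == 0))

  ph <- co0$phenotypes
  expect_true(all(ph$phenotype == as.integer(ph$liability > ph$threshold)))

  # realized genetic variance is h2 exactly (rescaled effects)
  co <- small_cohort(n = 1000, m = 200, h2 = 0.5, n_qtl = 20, seed = 3)
  expect_equal(var(co$phenotypes$genetic_value), 0.5, tolerance = 1e-10)

  # prevalence fixed by construction: K = 0.44 on n = 183 -> 80 or 81 cases
  co183 <- small_cohort(n = 183, m = 100, prevalence = 0.44, seed = 17)
  expect_true(sum(co183$phenotypes$phenotype) %in% c(80L, 81L))
})

test_that("heritability calibration holds across replicates", {
  realized <- vapply(1:20, function(s) {
    co <- small_cohort(n = 300, m = 150, h2 = 0.3, n_qtl = 10, seed = s)
    var(co$phenotypes$genetic_value)
  }, numeric(1))
  expect_lt(abs(mean(realized) - 0.3), 0.05)
})

test_that("sweeps overwrite the core as specified", {
  cfg <- sim_config(n_individuals = 100, n_snps = 300, n_chromosomes = 1,
                    seed = 19)
  haps <- simulate_haplotypes(cfg)

  full <- apply_sweep(haps, position = haps$positions[150], f = 1,
                      core_length = 30, seed = 2)
  core <- attr(full, "sweep_core")
  expect_equal(length(unique(apply(full$matrix[, core], 1, paste,
                                   collapse = ""))), 1L)
  # H12 computed exactly over the fixed core window equals 1
  core_haps <- toy_haps(full$matrix[, core])
  expect_equal(h12(core_haps, window_snps = length(core))$h12, 1)

  expect_identical(apply_sweep(haps, haps$positions[150], f = 0,
                               core_length = 30), haps)

  part <- apply_sweep(haps, position = haps$positions[150], f = 0.6,
                      core_length = 50, seed = 4)
  core <- attr(part, "sweep_core")
  classes <- table(apply(part$matrix[, core], 1, paste, collapse = ""))
  expect_gte(max(classes) / nrow(part$matrix), 0.6)

  expect_error(apply_sweep(haps, haps$positions[2], f = 0.5,
                           core_length = 100), "beyond")
})

test_that("configs are validated", {
  expect_error(sim_config(h2_liability = 1), "h2_liability")
  expect_error(sim_config(n_qtl = 100, n_snps = 50), "n_qtl")
  expect_error(simulate_pedigree(0), "n_founders")
  expect_error(
    simulate_liability_phenotypes(small_cohort(20, 30)$genotypes, h2 = 1,
                                  K = 0.4), "h2")
})
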