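test_that("site diversity follows the pairwise-difference formula", {
  h <- toy_haps(rbind(c(1, 0), c(1, 0), c(0, 0), c(0, 1)))
  # counts (2,2) of 4 -> 2*2*2/(4*3)
  expect_equal(site_pi(h)[1], 2 * 2 * 2 / (4 * 3))
  expect_equal(site_pi(toy_haps(matrix(0, 4, 1)))[1], 0)
  expect_equal(site_pi(toy_haps(matrix(c(0, 1), 2, 1)))[1], 1)
})

test_that("delta-pi is antisymmetric and zero for identical groups", {
  co <- small_cohort(n = 60, m = 100, chromosomes = 1, seed = 81)
  a <- co$case_haplotypes; b <- co$control_haplotypes
  expect_true(all(delta_pi(a, a)$delta_pi == 0))
  expect_equal(delta_pi(a, b)$delta_pi, -delta_pi(b, a)$delta_pi)
})

test_that("EHH starts at one, drops with splits, and never increases", {
  H <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(0, 0, 0))
  e <- ehh(toy_haps(H), core_index = 2, core_allele = 1)
  expect_equal(e[2], 1)
  expect_equal(e, c(1, 1, 1))   # three carriers identical over the span

  # two carriers differing at the adjacent site: EHH hits 0 there
  H2 <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 0))
  e2 <- ehh(toy_haps(H2), core_index = 2, core_allele = 1)
  expect_equal(e2[1], 0)
  expect_equal(e2[3], 0)

  expect_error(ehh(toy_haps(H2), core_index = 1, core_allele = 1),
               "fewer than two")

  co <- small_cohort(n = 40, m = 60, chromosomes = 1, seed = 82)
  em <- ehh(co$haplotypes, core_index = 30, core_allele = 1)
  expect_true(all(diff(em[30:60]) <= 1e-12))
  expect_true(all(diff(rev(em[1:30])) <= 1e-12))
})

test_that("H12 matches hand-computed haplotype spectra", {
  all_same <- toy_haps(matrix(1, 10, 4))
  expect_equal(h12(all_same, 4)$h12, 1)

  # frequencies (0.5, 0.5)
  two <- toy_haps(rbind(matrix(0, 5, 3), matrix(1, 5, 3)))
  expect_equal(h12(two, 3)$h12, 1)

  # frequencies (0.5, 0.25, 0.25) -> 0.75^2 + 0.25^2
  spec <- toy_haps(rbind(matrix(0, 4, 2),
                         matrix(c(1, 0), 2, 2, byrow = TRUE),
                         matrix(1, 2, 2)))
  expect_equal(h12(spec, 2)$h12, 0.625)
})

test_that("standardized haplotype scores have per-bin mean 0 and SD 1", {
  co <- small_cohort(n = 80, m = 250, chromosomes = 1, seed = 83,
                     ld_rho = 0.85)
  sc <- ihs(co$haplotypes, n_bins = 5)
  ok <- !is.na(sc$ihs)
  expect_gt(sum(ok), 50)
  bins <- cut(sc$freq_derived[ok], seq(0, 1, length.out = 6),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    v <- sc$ihs[ok][bins == b]
    if (length(v) >= 2) {
      expect_lt(abs(mean(v)), 1e-6)
      expect_equal(stats::sd(v), 1, tolerance = 1e-6)
    }
  }
  # nSL ignores the physical map entirely
  h10 <- co$haplotypes
  h10$positions <- h10$positions * 10L
  expect_equal(nsl(co$haplotypes)$nsl, nsl(h10)$nsl)
})

test_that("fractional-rank p-values follow the rank formula", {
  x <- c(5, 3, 9, 1, 7, 2, 8, 4, 6)   # 9 distinct values
  p <- fractional_rank_pvalues(x, "right")
  expect_equal(p[x == 9], 1 - 9 / 10)
  expect_equal(p[x == 5], 0.5)        # median of odd-length distinct vector
  expect_equal(fractional_rank_pvalues(x, "left"),
               fractional_rank_pvalues(-x, "right"))
  expect_true(all(p > 0 & p < 1))
  expect_equal(unique(fractional_rank_pvalues(rep(2, 10), "right")), 0.5)
})

test_that("MCD correlation is robust and flags degenerate input", {
  set.seed(84)
  X <- cbind(a = rnorm(5000), b = rnorm(5000))
  R <- robust_correlation(X, seed = 1)
  expect_lt(abs(R[1, 2]), 0.1)
  expect_equal(diag(R), c(a = 1, b = 1))

  Xd <- cbind(a = X[, 1], b = X[, 1])
  expect_warning(Rd <- robust_correlation(Xd, seed = 1), "singular")
  expect_equal(Rd[1, 2], 1, tolerance = 1e-8)

  expect_error(robust_correlation(cbind(a = rnorm(100), b = rep(1, 100))),
               "constant")

  # contamination: robust estimate stays closer to the clean correlation
  set.seed(85)
  n <- 2000
  z <- rnorm(n)
  clean <- cbind(a = z + rnorm(n), b = z + rnorm(n))
  r_clean <- cor(clean)[1, 2]
  dirty <- clean
  out_idx <- 1:200
  dirty[out_idx, ] <- cbind(rnorm(200, 8), rnorm(200, -8))
  r_classical <- cor(dirty)[1, 2]
  r_robust <- robust_correlation(dirty, seed = 2)[1, 2]
  expect_lt(abs(r_robust - r_clean), abs(r_classical - r_clean))
})

test_that("DCMS weighting matches its closed forms", {
  # single statistic at p = 0.5
  expect_equal(dcms(matrix(0.5), matrix(1)), 0)
  # perfectly correlated pair, both p = 0.1
  R2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(dcms(matrix(c(0.1, 0.1), 1), R2), log(9))
  # independent pair
  expect_equal(dcms(matrix(c(0.1, 0.1), 1), diag(2)), 2 * log(9))
  # single-statistic reduction: DCMS is exactly the log-odds score
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(dcms(matrix(p, ncol = 1), matrix(1)), log((1 - p) / p))
  expect_error(dcms(matrix(c(0, 0.5), 1), diag(2)), "strictly")
})

test_that("robust-normal DCMS p-values are calibrated and equivariant", {
  set.seed(86)
  x <- rnorm(10000)
  fit <- dcms_pvalues(x)
  expect_lt(abs(fit$location), 0.05)
  expect_equal(fit$scale, 1, tolerance = 0.05)
  shifted <- dcms_pvalues(x + 3)
  expect_equal(shifted$location, fit$location + 3, tolerance = 0.02)
  expect_equal(shifted$p, fit$p, tolerance = 1e-6)
  expect_equal(which.min(fit$p), which.max(x))
})

test_that("the composite scan is symmetric for identical groups", {
  co <- small_cohort(n = 60, m = 400, chromosomes = 1, seed = 87)
  # identical groups: delta-pi is constant and dropped with a warning
  # (once per group)
  w <- testthat::capture_warnings(
    same <- selection_scan(co$case_haplotypes, co$case_haplotypes, seed = 3)
  )
  expect_match(w, "constant", all = TRUE)
  expect_equal(same$case$dcms, same$control$dcms)
  expect_equal(dim(same$correlations$case), c(4L, 4L))

  four <- selection_scan(co$case_haplotypes, co$control_haplotypes,
                         statistics = c("delta_pi", "nsl", "h12", "ihs"),
                         seed = 3)
  expect_equal(dim(four$correlations$case), c(4L, 4L))
})

test_that("haplotype row order never changes the statistics", {
  co <- small_cohort(n = 50, m = 120, chromosomes = 1, seed = 88)
  h <- co$case_haplotypes
  set.seed(89)
  hp <- h; hp$matrix <- h$matrix[sample(nrow(h$matrix)), ]
  expect_equal(site_pi(h), site_pi(hp))
  expect_equal(h12(h, 20)$h12, h12(hp, 20)$h12)
  expect_equal(nsl(h)$nsl, nsl(hp)$nsl)
})

test_that("a case-only sweep surfaces in the case DCMS ranks", {
  hits <- vapply(1:3, function(rep) {
    sweep_cfg <- list(chromosome = "chr1", position = 1e6, fraction = 0.8,
                      core_length = 40)
    co <- small_cohort(n = 90, m = 400, chromosomes = 1, seed = 90 + rep,
                       sweep = sweep_cfg, ld_rho = 0.9)
    sel <- selection_scan(co$case_haplotypes, co$control_haplotypes,
                          seed = 5)
    core <- attr(co$case_haplotypes, "sweep_core")
    case_rank <- min(rank(-sel$case$dcms)[core], na.rm = TRUE)
    ctrl_rank <- min(rank(-sel$control$dcms)[core], na.rm = TRUE)
    (case_rank <= 0.05 * 400) && (case_rank < ctrl_rank)
  }, logical(1))
  expect_gte(sum(hits), 2)
})
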