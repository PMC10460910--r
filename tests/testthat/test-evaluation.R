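test_that("stratified folds have balanced sizes and are reproducible", {
  f <- kfold_split(183, k = 5, seed = 1)
  expect_setequal(as.integer(table(f)), c(37L, 37L, 37L, 36L, 36L))

  y10 <- rep(c(0, 1), 5)
  f10 <- kfold_split(10, k = 5, stratify_labels = y10, seed = 2)
  for (fold in 1:5) {
    expect_equal(sort(y10[f10 == fold]), c(0, 1))
  }
  expect_identical(kfold_split(50, 5, seed = 9), kfold_split(50, 5, seed = 9))
  expect_warning(kfold_split(10, 5, stratify_labels = c(rep(0, 8), 1, 1)),
                 "smaller than k")
})

test_that("the Robertson transformation matches its closed forms", {
  expect_equal(as.numeric(robertson_r2(0, 0.3)), 0)
  # K = 0.5: factor K(1-K)/phi(0)^2 = 0.25 * 2*pi = pi/2
  expect_equal(as.numeric(robertson_r2(0.1, 0.5)), 0.1 * pi / 2)
  expect_equal(as.numeric(robertson_r2(0.2, 0.31)),
               2 * as.numeric(robertson_r2(0.1, 0.31)))
  expect_error(robertson_r2(-0.1, 0.5), "nonnegative")
  clipped <- robertson_r2(0.9, 0.5)
  expect_equal(as.numeric(clipped), 1)
  expect_true(attr(clipped, "clipped"))
})

test_that("liability R2 formulas follow their variance ratios", {
  eta1 <- c(-1, 1) * sqrt(1 / 2)          # var = 1
  expect_equal(liability_r2_probit(eta1), 0.5)
  expect_equal(liability_r2_probit(rep(3, 5)), 0)
  eta3 <- c(-1, 1) * sqrt(3 / 2)          # var = 3
  expect_equal(liability_r2_probit(eta3), 0.75)

  etal <- c(-1, 1) * sqrt(pi^2 / 6)       # var = pi^2/3
  expect_equal(liability_r2_logit(etal), 0.5)
  expect_equal(liability_r2_logit(c(-1, 1) * sqrt(1 / 2)),
               1 / (1 + pi^2 / 3), tolerance = 1e-6)
  # both are strictly increasing in var(eta)
  vs <- c(0.1, 0.5, 1, 2, 5)
  pr <- sapply(vs, function(v) liability_r2_probit(c(-1, 1) * sqrt(v / 2)))
  lo <- sapply(vs, function(v) liability_r2_logit(c(-1, 1) * sqrt(v / 2)))
  expect_true(all(diff(pr) > 0) && all(diff(lo) > 0))
  expect_true(all(pr < 1) && all(lo < 1))
})

test_that("ensemble probabilities are means bounded by the components", {
  tab <- tibble::tibble(m1 = c(0.7, 0.2), m2 = c(0.7, 0.8))
  ens <- ensemble_predict(tab)
  expect_equal(ens$table$ensemble, c(0.7, 0.5))
  expect_true(all(ens$table$ensemble >= pmin(tab$m1, tab$m2) &
                    ens$table$ensemble <= pmax(tab$m1, tab$m2)))
  expect_error(ensemble_predict(tibble::tibble(m1 = c(0.5, NA))), "missing")
})

test_that("threshold tuning maximizes accuracy with the 0.5-first tie rule", {
  fit <- tune_threshold(c(0.2, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(fit$threshold, 0.5)
  expect_equal(fit$metric_value, 1)

  inv <- tune_threshold(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
  expect_true(inv$degenerate)

  same <- tune_threshold(rep(0.3, 10), rep(c(0, 1), 5))
  expect_equal(same$threshold, 0.5)
})

test_that("cross-validation is leakage-free and reproducible", {
  co <- small_cohort(n = 100, m = 80, seed = 98, h2 = 0.4, n_qtl = 5,
                     ld_rho = 0.2)
  g <- co$genotypes
  y <- co$phenotypes$phenotype
  fold_preview <- kfold_split(100, k = 4, stratify_labels = y, seed = 42)
  # plant a SNP that matches the phenotype perfectly in fold 1 only and is
  # pure noise elsewhere: a leak-free CV must not select it for fold 1
  set.seed(99)
  planted <- ifelse(fold_preview == 1, y, rbinom(100, 1, 0.5)) * 2L
  g$values[, 40] <- planted
  cv <- crossvalidate_models(g, y, models = "LASSO", k = 4,
                             fraction_grid = 0.05, seed = 42)
  sel_f1 <- cv$selected$snp[cv$selected$fold == 1]
  expect_false(g$variants$id[40] %in% sel_f1)

  cv2 <- crossvalidate_models(g, y, models = "LASSO", k = 4,
                              fraction_grid = 0.05, seed = 42)
  expect_identical(cv$folds, cv2$folds)
  expect_true(all(cv$folds$r2_probit >= 0 & cv$folds$r2_probit <= 1))
})

test_that("heritable data scores higher than null data in CV", {
  co_sig <- small_cohort(n = 300, m = 150, seed = 100, h2 = 0.6, n_qtl = 10,
                         ld_rho = 0.2)
  co_nul <- small_cohort(n = 300, m = 150, seed = 100, h2 = 0, n_qtl = 0,
                         ld_rho = 0.2)
  mcmc <- list(n_iter = 1200, burnin = 300, thin = 3)
  cv_sig <- crossvalidate_models(co_sig$genotypes,
                                 co_sig$phenotypes$phenotype,
                                 models = "BRR", k = 3,
                                 fraction_grid = 0.1, mcmc = mcmc, seed = 7)
  cv_nul <- crossvalidate_models(co_nul$genotypes,
                                 co_nul$phenotypes$phenotype,
                                 models = "BRR", k = 3,
                                 fraction_grid = 0.1, mcmc = mcmc, seed = 7)
  expect_gt(mean(cv_sig$folds$r2_obs), mean(cv_nul$folds$r2_obs))
})
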