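test_that("top-SNP selection uses the floor convention with genome-order ties", {
  m <- 447630
  fake <- tibble::tibble(chrom = "chr1", pos = seq_len(m),
                         p = rep(0.5, m))
  expect_length(select_top_snps(fake, 0.005), 2238L)
  expect_length(select_top_snps(fake, 0.01), 4476L)
  expect_length(select_top_snps(fake, 0.02), 8952L)
  expect_length(select_top_snps(fake, 0.03), 13428L)

  small <- tibble::tibble(chrom = "chr1", pos = 1:100,
                          p = c(rep(0.001, 3), runif(97, 0.1, 1)))
  expect_length(select_top_snps(small, 1.0), 100L)
  expect_equal(select_top_snps(small, 0.03), 1:3)
  expect_error(select_top_snps(small, 0.001), "zero")
})

test_that("fixed-variance BRR matches the ridge closed form on the latents", {
  set.seed(91)
  n <- 40; m <- 30
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  b_true <- rnorm(m, 0, 0.3)
  y <- as.integer(X %*% b_true + rnorm(n) > mean(X %*% b_true))
  s2 <- 0.2
  spec <- bayes_model_spec("BRR", S_beta = s2, fix_variances = TRUE,
                           n_iter = 12000, burnin = 2000, thin = 2, seed = 5)
  fit <- fit_bayes_probit(X, y, spec = spec)
  # ridge solution at the posterior-mean latent liabilities
  lbar <- fit$latent_mean - fit$mu
  Xc <- X
  ridge <- solve(crossprod(Xc) + diag(1 / s2, m), crossprod(Xc, lbar))
  expect_gt(cor(fit$effects$beta, as.numeric(ridge)), 0.98)
  expect_equal(fit$effects$beta, as.numeric(ridge), tolerance = 0.1)
})

test_that("an intercept-only probit model centres on the case fraction", {
  y <- rep(c(0L, 1L), 40)
  spec <- bayes_model_spec("BRR", n_iter = 6000, burnin = 1000, thin = 2,
                           seed = 7)
  fit <- fit_bayes_probit(matrix(numeric(0), nrow = 80, ncol = 0), y,
                          spec = spec)
  expect_equal(mean(pnorm(fit$draws$`(Intercept)`)), 0.5, tolerance = 0.05)
})

test_that("chains are deterministic and symmetric under label flips", {
  co <- small_cohort(n = 80, m = 60, seed = 92, h2 = 0.5, n_qtl = 5)
  X <- co$genotypes$values
  y <- co$phenotypes$phenotype
  spec <- bayes_model_spec("BayesC", n_iter = 1500, burnin = 300, thin = 3,
                           seed = 11)
  f1 <- fit_bayes_probit(X, y, spec = spec)
  f2 <- fit_bayes_probit(X, y, spec = spec)
  expect_identical(f1$draws, f2$draws)

  # flipping the labels negates the genetic linear predictor
  f3 <- fit_bayes_probit(X, 1L - y, spec = spec)
  g1 <- as.numeric(X %*% f1$effects$beta)
  g3 <- as.numeric(X %*% f3$effects$beta)
  expect_lt(cor(g1, -g3) * -1, -0.8)
})

test_that("BayesC with pi forced near zero approaches BRR", {
  co <- small_cohort(n = 100, m = 50, seed = 93, h2 = 0.5, n_qtl = 5)
  X <- co$genotypes$values
  y <- co$phenotypes$phenotype
  brr <- fit_bayes_probit(X, y, spec = bayes_model_spec(
    "BRR", n_iter = 4000, burnin = 1000, thin = 2, seed = 13))
  bc0 <- fit_bayes_probit(X, y, spec = bayes_model_spec(
    "BayesC", pi0_shape = 2000, pi0_mean = 0.001,
    n_iter = 4000, burnin = 1000, thin = 2, seed = 13))
  expect_gt(cor(brr$effects$beta, bc0$effects$beta), 0.95)
})

test_that("BRR shrinks toward zero as the prior scale vanishes", {
  co <- small_cohort(n = 60, m = 40, seed = 94, h2 = 0.5, n_qtl = 5)
  X <- co$genotypes$values
  y <- co$phenotypes$phenotype
  norms <- vapply(c(0.5, 0.01, 1e-4), function(S) {
    fit <- fit_bayes_probit(X, y, spec = bayes_model_spec(
      "BRR", S_beta = S, nu_beta = 50, n_iter = 1500, burnin = 300,
      thin = 3, seed = 17))
    sqrt(sum(fit$effects$beta^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("PRS predictions separate cases on heritable data", {
  co <- small_cohort(n = 150, m = 120, seed = 95, h2 = 0.5, n_qtl = 10)
  X <- co$genotypes$values
  colnames(X) <- co$genotypes$variants$id
  y <- co$phenotypes$phenotype
  fit <- fit_bayes_probit(X, y, spec = bayes_model_spec(
    "BRR", n_iter = 2000, burnin = 500, thin = 5, seed = 19))
  pred <- predict_prs(fit, X)
  auc <- mean(outer(pred$probability[y == 1], pred$probability[y == 0],
                    ">") + 0.5 * outer(pred$probability[y == 1],
                                       pred$probability[y == 0], "=="))
  expect_gt(auc, 0.5)
  # shifting the intercept shifts every linear predictor by c
  fit2 <- fit
  fit2$mu <- fit$mu + 0.7
  expect_equal(predict_prs(fit2, X)$eta, pred$eta + 0.7)

  expect_error(predict_prs(fit, X[, 1:10]), "mismatch")
})

test_that("ML baselines behave sensibly on signal and noise", {
  co <- small_cohort(n = 120, m = 60, seed = 96, h2 = 0.6, n_qtl = 5)
  X <- co$genotypes$values
  colnames(X) <- co$genotypes$variants$id
  y <- co$phenotypes$phenotype
  las <- fit_ml_baselines(X, y, model = "LASSO", cv_folds = 5, seed = 3)
  las2 <- fit_ml_baselines(X, y, model = "LASSO", cv_folds = 5, seed = 3)
  expect_equal(las$probabilities, las2$probabilities)
  expect_true(all(las$probabilities >= 0 & las$probabilities <= 1))

  # EN grid includes alpha = 0.9; with one-alpha grid it matches glmnet
  en <- fit_ml_baselines(X, y, model = "EN", cv_folds = 5, seed = 3)
  expect_true(en$hyperparameters$alpha %in% c(0.1, 0.25, 0.5, 0.75, 0.9))

  # RF on pure noise: held-out accuracy near the majority-class rate
  set.seed(97)
  Xn <- matrix(rbinom(100 * 30, 2, 0.4), 100, 30)
  yn <- rep(c(0L, 1L), each = 50)
  rf <- fit_ml_baselines(Xn[1:80, ], yn[1:80], model = "RF", cv_folds = 4,
                         seed = 5)
  acc <- mean((rf$predict_fn(Xn[81:100, ]) > 0.5) == yn[81:100])
  expect_gte(acc, 0.25)
  expect_lte(acc, 0.75)
})
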