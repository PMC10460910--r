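#' Select the top fraction of SNPs from a GWAS scan
#'
#' `k = floor(fraction * m)` SNPs with the smallest p-values; ties broken
#' by chromosome then position for a deterministic list.
#'
#' @param gwas_result A `gwas_result` (needs columns `chrom`, `pos`, `p`).
#' @param fraction Fraction of SNPs in (0, 1].
#' @return Integer vector of row indices into the scan (equivalently SNP
#'   columns), sorted by genome order.
#' @export
select_top_snps <- function(gwas_result, fraction) {
  check_fraction(fraction, "fraction", 0, 1, lo_open = TRUE)
  m <- nrow(gwas_result)
  k <- floor(fraction * m)
  if (k < 1) ta_stop("fraction selects zero SNPs")
  ord <- order(gwas_result$p, gwas_result$chrom, gwas_result$pos)
  sort(ord[seq_len(k)])
}

#' Specification of a Bayesian probit whole-genome regression model
#'
#' @param model One of `"BRR"`, `"BayesB"`, `"BayesC"`, `"BL"`.
#' @param nu_beta,S_beta Scaled-inverse-chi-squared prior on marker
#'   variances. `S_beta = NULL` applies the R2 heuristic: the prior mode of
#'   the total marker variance matches `r2_target` of the (unit) liability
#'   variance spread over the sum of marker variances.
#' @param pi0_shape,pi0_mean Beta prior on the null-mixture probability pi
#'   (BayesB/BayesC): `pi ~ Beta(pi0_shape * pi0_mean,
#'   pi0_shape * (1 - pi0_mean))`.
#' @param bl_shape Gamma shape s for lambda^2 (Bayesian LASSO, default
#'   1.1); the rate follows `r = (s - 1) / (2 (1 - R2) / R2 * MS_x)`.
#' @param r2_target R2 used by the prior-scale heuristics (default 0.5).
#' @param fix_variances If `TRUE`, marker variances (and pi / lambda) stay
#'   at their starting values instead of being updated — useful for
#'   closed-form checks against the ridge solution.
#' @param n_iter,burnin,thin,seed MCMC schedule.
#' @return A `bayes_model_spec` list.
#' @export
bayes_model_spec <- function(model = c("BRR", "BayesB", "BayesC", "BL"),
                             nu_beta = 5, S_beta = NULL,
                             pi0_shape = 5, pi0_mean = 0.5,
                             bl_shape = 1.1, r2_target = 0.5,
                             fix_variances = FALSE,
                             n_iter = 20000L, burnin = 2000L, thin = 5L,
                             seed = 1L) {
  model <- match.arg(model)
  stopifnot(nu_beta > 0, is.null(S_beta) || S_beta > 0, bl_shape > 1)
  check_fraction(pi0_mean, "pi0_mean")
  structure(list(model = model, nu_beta = nu_beta, S_beta = S_beta,
                 pi0_shape = pi0_shape, pi0_mean = pi0_mean,
                 bl_shape = bl_shape, r2_target = r2_target,
                 fix_variances = isTRUE(fix_variances),
                 n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "bayes_model_spec")
}

# inverse-Gaussian sampler (Michael-Schucany-Haas)
rinvgauss1 <- function(n, mean, shape) {
  nu <- rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  z <- runif(n)
  ifelse(z <= mean / (mean + x), x, mean^2 / x)
}

#' Bayesian probit whole-genome regression (Gibbs sampler)
#'
#' Data-augmented probit Gibbs sampler with residual variance fixed at 1
#' and the case threshold at 0. Marker-effect priors by model: shared
#' normal variance (BRR), per-marker variances with a point mass at zero
#' (BayesB), shared variance with a point mass (BayesC), or
#' double-exponential shrinkage via per-marker exponential-scale mixing
#' with a Gamma hyperprior on lambda^2 (BL). The intercept and any
#' covariates get flat priors; variances get scaled-inverse-chi-squared
#' full-conditional updates; pi gets a Beta full conditional.
#'
#' @param geno_subset Numeric matrix (samples x selected SNPs, no missing)
#'   or a `genotype_matrix`.
#' @param y 0/1 phenotype vector.
#' @param covariates Optional unpenalized covariates (e.g. sex).
#' @param spec A [bayes_model_spec()].
#' @return Object of class `bayes_probit_fit`: scalar `draws` tibble
#'   (sigma2_beta or its mean, pi, lambda2, mu, covariate effects, h2_snp),
#'   posterior-mean `effects` tibble (beta, inclusion probability), the
#'   spec, and the training SNP ids.
#' @export
fit_bayes_probit <- function(geno_subset, y, covariates = NULL, spec) {
  stopifnot(inherits(spec, "bayes_model_spec"))
  X <- if (inherits(geno_subset, "genotype_matrix")) {
    geno_subset$values
  } else as.matrix(geno_subset)
  if (anyNA(X)) ta_stop("missing genotypes in the training subset")
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), length(y) == nrow(X))
  n <- nrow(X); m <- ncol(X)
  snp_ids <- colnames(X) %||% paste0("snp_", seq_len(m))
  W <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  q <- ncol(W)
  WtW_inv <- solve(crossprod(W))
  WtW_chol <- chol(WtW_inv)
  xx <- colSums(X^2)
  const_snp <- if (m > 0) {
    xx < 1e-12 | apply(X, 2, sd) < 1e-12
  } else logical(0)
  ms_x <- if (m > 0) sum(apply(X, 2, var)) else 1
  if (m > 0 && ms_x <= 0) ta_stop("all SNP columns are constant")

  nu <- spec$nu_beta
  S0 <- spec$S_beta %||%
    (spec$r2_target / ms_x * (nu + 2) / nu /
       (if (spec$model %in% c("BayesB", "BayesC")) 1 - spec$pi0_mean else 1))
  a_pi <- spec$pi0_shape * spec$pi0_mean
  b_pi <- spec$pi0_shape * (1 - spec$pi0_mean)
  bl_rate <- (spec$bl_shape - 1) /
    (2 * (1 - spec$r2_target) / spec$r2_target * ms_x)

  set.seed(spec$seed)
  beta <- numeric(m)
  alpha <- numeric(q)
  sigma2_beta <- rep(S0, m)          # per-marker (shared models use [1])
  shared_s2 <- S0
  pi_null <- spec$pi0_mean
  lambda2 <- spec$bl_shape / bl_rate
  tau2 <- rep(1, m)
  incl <- rep(TRUE, m)
  eta <- as.numeric(W %*% alpha)
  r <- numeric(n)                    # residual l - W alpha - X beta
  keep <- seq(spec$burnin + spec$thin, spec$n_iter, by = spec$thin)
  keep_flag <- logical(spec$n_iter); keep_flag[keep] <- TRUE
  n_keep <- length(keep)
  beta_sum <- numeric(m); incl_sum <- numeric(m); l_sum <- numeric(n)
  dr_s2 <- numeric(n_keep); dr_pi <- numeric(n_keep)
  dr_l2 <- numeric(n_keep); dr_h2 <- numeric(n_keep)
  dr_alpha <- matrix(0, n_keep, q)
  ki <- 0L
  eps <- 1e-12
  mix <- spec$model %in% c("BayesB", "BayesC")

  l <- ifelse(y == 1L, 0.5, -0.5)
  r <- l - eta
  for (it in seq_len(spec$n_iter)) {
    # latent liabilities
    mu_l <- l - r                    # current linear predictor W a + X b
    u01 <- runif(n)
    plo <- ifelse(y == 1L, pnorm(-mu_l), 0)
    phi_ <- ifelse(y == 0L, pnorm(-mu_l), 1)
    uu <- pmin(pmax(plo + u01 * (phi_ - plo), eps), 1 - eps)
    l_new <- mu_l + qnorm(uu)
    r <- r + (l_new - l)
    l <- l_new
    # intercept + covariates (flat prior)
    rw <- r + as.numeric(W %*% alpha)
    ahat <- WtW_inv %*% crossprod(W, rw)
    alpha_new <- as.numeric(ahat + t(WtW_chol) %*% rnorm(q))
    r <- rw - as.numeric(W %*% alpha_new)
    alpha <- alpha_new
    # marker effects
    s2_vec <- switch(spec$model,
                     BRR = rep(shared_s2, m),
                     BayesC = rep(shared_s2, m),
                     BayesB = sigma2_beta,
                     BL = tau2)
    for (j in seq_len(m)) {
      if (const_snp[j]) { beta[j] <- 0; incl[j] <- FALSE; next }
      xj <- X[, j]
      rhs <- sum(xj * r) + xx[j] * beta[j]
      Cj <- xx[j] + 1 / s2_vec[j]
      if (mix) {
        log_bf <- 0.5 * rhs^2 / Cj - 0.5 * log(s2_vec[j] * Cj)
        p_in <- 1 / (1 + pi_null / (1 - pi_null) * exp(-log_bf))
        incl[j] <- runif(1) < p_in
      } else incl[j] <- TRUE
      new_b <- if (incl[j]) rhs / Cj + rnorm(1) / sqrt(Cj) else 0
      if (new_b != beta[j]) {
        r <- r - xj * (new_b - beta[j])
        beta[j] <- new_b
      }
    }
    # variance updates
    if (spec$fix_variances) {
      # priors stay at their configured values (closed-form checks)
    } else if (spec$model == "BRR") {
      shared_s2 <- (nu * S0 + sum(beta^2)) / rchisq(1, nu + m)
    } else if (spec$model == "BayesC") {
      m_in <- sum(incl)
      shared_s2 <- (nu * S0 + sum(beta[incl]^2)) / rchisq(1, nu + m_in)
    } else if (spec$model == "BayesB") {
      sigma2_beta <- (nu * S0 + beta^2) / rchisq(m, nu + as.numeric(incl))
    } else {                          # BL
      bj <- pmax(abs(beta), 1e-8)
      tau2 <- 1 / rinvgauss1(m, mean = sqrt(lambda2) / bj, shape = lambda2)
      lambda2 <- rgamma(1, shape = spec$bl_shape + m,
                        rate = bl_rate + sum(tau2) / 2)
    }
    if (mix && !spec$fix_variances) {
      m_in <- sum(incl & !const_snp)
      m_out <- sum(!incl & !const_snp)
      pi_null <- rbeta(1, a_pi + m_out, b_pi + m_in)
      pi_null <- min(max(pi_null, 1e-4), 1 - 1e-4)
    }
    if (keep_flag[it]) {
      ki <- ki + 1L
      beta_sum <- beta_sum + beta
      incl_sum <- incl_sum + incl
      l_sum <- l_sum + l
      g <- as.numeric(X %*% beta)
      vg <- var(g)
      dr_h2[ki] <- vg / (vg + 1)
      dr_s2[ki] <- if (spec$model == "BayesB") mean(sigma2_beta)
                   else if (spec$model == "BL") mean(tau2)
                   else shared_s2
      dr_pi[ki] <- if (mix) pi_null else NA_real_
      dr_l2[ki] <- if (spec$model == "BL") lambda2 else NA_real_
      dr_alpha[ki, ] <- alpha
    }
  }
  draws <- bind_cols(
    tibble(iteration = keep, sigma2_beta = dr_s2, pi = dr_pi,
           lambda2 = dr_l2, h2_snp = dr_h2),
    as_tibble(dr_alpha, .name_repair = ~ colnames(W))
  )
  structure(list(
    draws = draws,
    effects = tibble(snp = snp_ids, beta = beta_sum / n_keep,
                     pip = incl_sum / n_keep),
    spec = spec, snp_ids = snp_ids,
    latent_mean = l_sum / n_keep,
    mu = mean(draws$`(Intercept)`),
    covariate_names = colnames(W)[-1],
    alpha = colMeans(dr_alpha)
  ), class = "bayes_probit_fit")
}

#' @export
print.bayes_probit_fit <- function(x, ...) {
  cat(sprintf("<bayes_probit_fit> %s, %d SNPs, %d retained draws\n",
              x$spec$model, nrow(x$effects), nrow(x$draws)))
  invisible(x)
}

#' @export
tidy.bayes_probit_fit <- function(x, ...) x$effects

#' @export
glance.bayes_probit_fit <- function(x, ...) {
  tibble(model = x$spec$model, n_snps = nrow(x$effects),
         n_draws = nrow(x$draws), mean_h2_snp = mean(x$draws$h2_snp),
         mean_pi = mean(x$draws$pi))
}

#' Polygenic risk prediction from a fitted Bayesian probit model
#'
#' `eta = mu + covariates alpha + G beta` with posterior-mean effects;
#' case probability is `Phi(eta)`.
#'
#' @param fit A `bayes_probit_fit`.
#' @param geno Matrix or `genotype_matrix` with the training SNP set (same
#'   columns, same order or identifiable by column name).
#' @param covariates Covariate values matching the training covariates.
#' @return Tibble: `eta`, `probability`.
#' @export
predict_prs <- function(fit, geno, covariates = NULL) {
  stopifnot(inherits(fit, "bayes_probit_fit"))
  G <- if (inherits(geno, "genotype_matrix")) geno$values else as.matrix(geno)
  if (ncol(G) != nrow(fit$effects)) {
    if (!is.null(colnames(G)) && all(fit$snp_ids %in% colnames(G))) {
      G <- G[, fit$snp_ids, drop = FALSE]
    } else {
      missing_ids <- setdiff(fit$snp_ids, colnames(G) %||% character())
      ta_stop(sprintf("SNP set mismatch; missing: %s",
                      paste(utils::head(missing_ids, 5), collapse = ", ")))
    }
  }
  eta <- fit$mu + as.numeric(G %*% fit$effects$beta)
  if (length(fit$covariate_names)) {
    if (is.null(covariates)) ta_stop("model was fitted with covariates")
    eta <- eta + as.numeric(as.matrix(covariates) %*%
                              fit$alpha[-1])
  }
  tibble(eta = eta, probability = pnorm(eta))
}

#' Off-the-shelf machine-learning baselines
#'
#' Random forest (randomForest), gradient boosting (xgboost), LASSO and
#' elastic net (glmnet). Hyperparameters are tuned by a grid search with
#' internal stratified k-fold cross-validation (glmnet's own cv path for
#' lambda; alpha tuned jointly for the elastic net). Deterministic under
#' `seed`.
#'
#' @param geno_subset Samples x SNPs matrix (or `genotype_matrix`).
#' @param y 0/1 phenotype vector.
#' @param covariates Optional covariates appended as predictors.
#' @param model `"RF"`, `"GBM"`, `"LASSO"` or `"EN"`.
#' @param cv_folds Internal CV folds for tuning (default 10).
#' @param seed RNG seed.
#' @return List of class `ml_baseline_fit`: `model` label, fitted object,
#'   chosen hyperparameters, `probabilities` (training set) and
#'   `predict_fn(newX)`.
#' @export
fit_ml_baselines <- function(geno_subset, y, covariates = NULL,
                             model = c("RF", "GBM", "LASSO", "EN"),
                             cv_folds = 10L, seed = 1L) {
  model <- match.arg(model)
  X <- if (inherits(geno_subset, "genotype_matrix")) {
    geno_subset$values
  } else as.matrix(geno_subset)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  colnames(X) <- make.names(colnames(X) %||% paste0("x", seq_len(ncol(X))),
                            unique = TRUE)
  y <- as.integer(y)
  cv_folds <- min(cv_folds, min(table(y)))
  set.seed(seed)
  foldid <- kfold_split(length(y), k = cv_folds, stratify_labels = y,
                        seed = seed)
  if (model %in% c("LASSO", "EN")) {
    alphas <- if (model == "LASSO") 1 else c(0.1, 0.25, 0.5, 0.75, 0.9)
    fits <- lapply(alphas, function(a) {
      glmnet::cv.glmnet(X, y, family = "binomial", alpha = a,
                        foldid = foldid, type.measure = "deviance")
    })
    best <- which.min(vapply(fits, function(f) min(f$cvm), numeric(1)))
    fit <- fits[[best]]
    predict_fn <- function(newX) {
      as.numeric(predict(fit, newx = as.matrix(newX), s = "lambda.min",
                         type = "response"))
    }
    hyper <- list(alpha = alphas[best], lambda = fit$lambda.min)
    obj <- fit
  } else if (model == "RF") {
    p <- ncol(X)
    mtry_grid <- unique(pmax(1L, floor(c(sqrt(p), p / 4, p / 2))))
    cv_err <- vapply(mtry_grid, function(mt) {
      errs <- vapply(seq_len(cv_folds), function(f) {
        tr <- foldid != f
        rf <- randomForest::randomForest(
          x = X[tr, , drop = FALSE], y = factor(y[tr]), mtry = mt,
          ntree = 300)
        pr <- predict(rf, X[!tr, , drop = FALSE], type = "prob")[, "1"]
        mean((pr - y[!tr])^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best_mtry <- mtry_grid[which.min(cv_err)]
    set.seed(seed)
    obj <- randomForest::randomForest(x = X, y = factor(y),
                                      mtry = best_mtry, ntree = 500)
    predict_fn <- function(newX) {
      newX <- as.matrix(newX)
      colnames(newX) <- colnames(X)
      predict(obj, newX, type = "prob")[, "1"]
    }
    hyper <- list(mtry = best_mtry, ntree = 500)
  } else {                             # GBM via xgboost
    grid <- expand.grid(max_depth = c(2L, 3L), nrounds = c(50L, 150L))
    cv_err <- vapply(seq_len(nrow(grid)), function(gi) {
      errs <- vapply(seq_len(cv_folds), function(f) {
        tr <- foldid != f
        bst <- xgboost::xgboost(
          data = X[tr, , drop = FALSE], label = y[tr],
          max_depth = grid$max_depth[gi], eta = 0.1,
          nrounds = grid$nrounds[gi], objective = "binary:logistic",
          nthread = 1, verbose = 0)
        pr <- predict(bst, X[!tr, , drop = FALSE])
        mean((pr - y[!tr])^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    gb <- grid[which.min(cv_err), ]
    set.seed(seed)
    obj <- xgboost::xgboost(data = X, label = y, max_depth = gb$max_depth,
                            eta = 0.1, nrounds = gb$nrounds,
                            objective = "binary:logistic", nthread = 1,
                            verbose = 0)
    predict_fn <- function(newX) predict(obj, as.matrix(newX))
    hyper <- as.list(gb)
  }
  structure(list(model = model, fit = obj, hyperparameters = hyper,
                 probabilities = predict_fn(X), predict_fn = predict_fn,
                 n_features = ncol(X)),
            class = "ml_baseline_fit")
}

#' @export
print.ml_baseline_fit <- function(x, ...) {
  cat(sprintf("<ml_baseline_fit> %s (%d features)\n", x$model, x$n_features))
  invisible(x)
}
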