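#' Stratified k-fold assignments
#'
#' Folds are stratified by label so sizes differ by at most one overall and
#' within each class; classes smaller than `k` trigger an unstratified
#' fallback with a warning.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param stratify_labels Optional label vector.
#' @param seed RNG seed.
#' @return Integer fold vector in `1..k`.
#' @export
kfold_split <- function(n, k = 5L, stratify_labels = NULL, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  if (k > n) ta_stop("more folds than samples")
  set.seed(seed)
  fold <- integer(n)
  if (!is.null(stratify_labels) && min(table(stratify_labels)) < k) {
    warn("a class is smaller than k; falling back to unstratified folds")
    stratify_labels <- NULL
  }
  if (is.null(stratify_labels)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    for (lv in unique(stratify_labels)) {
      idx <- which(stratify_labels == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

#' Robertson transformation of observed-scale R-squared
#'
#' `R2_liability = R2_observed * K (1 - K) / z^2` where `z` is the standard
#' normal density at the threshold quantile `qnorm(1 - K)`. Values above 1
#' are clipped (flagged via attribute `clipped`).
#'
#' @param r2_observed Observed-scale R-squared (>= 0).
#' @param K Prevalence in (0, 1).
#' @return Liability-scale R-squared in `[0, 1]`.
#' @export
robertson_r2 <- function(r2_observed, K) {
  if (any(r2_observed < 0)) ta_stop("observed R2 must be nonnegative")
  check_fraction(K, "K", 0, 1, lo_open = TRUE, hi_open = TRUE)
  z <- dnorm(qnorm(1 - K))
  out <- r2_observed * K * (1 - K) / z^2
  clipped <- out > 1
  out <- pmin(out, 1)
  attr(out, "clipped") <- any(clipped)
  out
}

#' Liability-scale R-squared from probit linear predictors
#'
#' `var(eta) / (var(eta) + 1)` (probit residual variance 1).
#'
#' @param eta_hat Linear predictor vector (>= 2 values).
#' @return R-squared in `[0, 1)`.
#' @export
liability_r2_probit <- function(eta_hat) {
  if (length(eta_hat) < 2) ta_stop("need at least two predictions")
  v <- var(eta_hat)
  if (!is.finite(v) || v == 0) return(0)
  v / (v + 1)
}

#' Liability-scale R-squared from logit linear predictors
#'
#' `var(eta) / (var(eta) + pi^2 / 3)`, the logistic residual variance
#' being `pi^2 / 3 = 3.2899`.
#'
#' @inheritParams liability_r2_probit
#' @export
liability_r2_logit <- function(eta_hat) {
  if (length(eta_hat) < 2) ta_stop("need at least two predictions")
  v <- var(eta_hat)
  if (!is.finite(v) || v == 0) return(0)
  v / (v + pi^2 / 3)
}

# linear predictors from probabilities on each liability scale
prob_to_eta <- function(prob, link = c("probit", "logit")) {
  link <- match.arg(link)
  p <- pmin(pmax(prob, 1e-6), 1 - 1e-6)
  if (link == "probit") qnorm(p) else stats::qlogis(p)
}

#' Cross-validated polygenic prediction over models and SNP fractions
#'
#' For every fold, the GWAS is re-run on the training samples only (GRM,
#' null mixed model, scan), the top SNP fraction is selected from that
#' training-fold scan, each requested model is trained on the training
#' folds, and the held-out samples are predicted — so SNP selection never
#' sees the held-out phenotypes. Reports observed-scale, probit-liability
#' and logit-liability R-squared per model x fraction x fold.
#'
#' @param geno A `genotype_matrix` (no missing values).
#' @param y 0/1 phenotype vector.
#' @param covariates Optional covariate matrix (e.g. sex).
#' @param models Character vector among BRR, BayesB, BayesC, BL, RF, GBM,
#'   LASSO, EN.
#' @param k Number of CV folds (default 5).
#' @param fraction_grid SNP fractions to evaluate (default
#'   `c(0.005, 0.01, 0.02, 0.03)`).
#' @param mcmc Bayesian MCMC schedule: list(n_iter, burnin, thin).
#' @param seed RNG seed.
#' @return A `cv_result`: `folds` tibble (model, fraction, fold, r2_obs,
#'   r2_probit, r2_logit), `summary` (means and SDs), `best_fraction`,
#'   `probabilities` (per individual x model at the best fraction).
#' @export
crossvalidate_models <- function(geno, y, covariates = NULL,
                                 models = c("BRR", "LASSO"),
                                 k = 5L,
                                 fraction_grid = c(0.005, 0.01, 0.02, 0.03),
                                 mcmc = list(n_iter = 3000L, burnin = 500L,
                                             thin = 5L),
                                 seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- as.integer(y)
  fold <- kfold_split(length(y), k = k, stratify_labels = y, seed = seed)
  bayes_models <- c("BRR", "BayesB", "BayesC", "BL")
  rows <- list()
  prob_store <- list()
  selected_store <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
      ta_stop("a fold contains a single class; reduce k")
    }
    geno_tr <- genotype_matrix(geno$values[tr, , drop = FALSE],
                               geno$variants, geno$samples[tr, ])
    grm_tr <- grm_vanraden(geno_tr)
    cov_tr <- if (!is.null(covariates)) {
      as.matrix(covariates)[tr, , drop = FALSE]
    }
    cov_te <- if (!is.null(covariates)) {
      as.matrix(covariates)[!tr, , drop = FALSE]
    }
    null_tr <- fit_null_lmm(y[tr], cov_tr, grm_tr)
    scan_tr <- gwas_scan(geno_tr, null_tr)
    for (fr in fraction_grid) {
      sel <- select_top_snps(scan_tr, fr)
      selected_store[[length(selected_store) + 1L]] <- tibble(
        fold = f, fraction = fr, snp = geno$variants$id[sel]
      )
      Xtr <- geno$values[tr, sel, drop = FALSE]
      Xte <- geno$values[!tr, sel, drop = FALSE]
      colnames(Xtr) <- colnames(Xte) <- geno$variants$id[sel]
      for (mod in models) {
        sd_seed <- derive_seed(seed, paste(mod, fr, f))
        if (mod %in% bayes_models) {
          spec <- bayes_model_spec(model = mod, n_iter = mcmc$n_iter,
                                   burnin = mcmc$burnin, thin = mcmc$thin,
                                   seed = sd_seed)
          fit <- fit_bayes_probit(Xtr, y[tr], covariates = cov_tr,
                                  spec = spec)
          pred <- predict_prs(fit, Xte, covariates = cov_te)
          prob <- pred$probability
          eta_p <- pred$eta
          eta_l <- prob_to_eta(prob, "logit")
        } else {
          fit <- fit_ml_baselines(Xtr, y[tr], covariates = cov_tr,
                                  model = mod, seed = sd_seed)
          newX <- if (!is.null(cov_te)) cbind(Xte, cov_te) else Xte
          prob <- fit$predict_fn(newX)
          eta_p <- prob_to_eta(prob, "probit")
          eta_l <- prob_to_eta(prob, "logit")
        }
        r2o <- if (sd(prob) == 0) 0 else cor(prob, y[!tr])^2
        rows[[length(rows) + 1L]] <- tibble(
          model = mod, fraction = fr, fold = f,
          r2_obs = r2o,
          r2_probit = liability_r2_probit(eta_p),
          r2_logit = liability_r2_logit(eta_l)
        )
        prob_store[[length(prob_store) + 1L]] <- tibble(
          model = mod, fraction = fr, fold = f,
          index = which(!tr), y = y[!tr], probability = prob
        )
      }
    }
  }
  folds <- bind_rows(rows)
  summary <- folds |>
    group_by(.data$model, .data$fraction) |>
    summarise(across(c("r2_obs", "r2_probit", "r2_logit"),
                     list(mean = mean, sd = sd)), .groups = "drop")
  best <- summary |>
    group_by(.data$fraction) |>
    summarise(score = mean(.data$r2_probit_mean), .groups = "drop")
  best_fraction <- best$fraction[which.max(best$score)]
  structure(list(folds = folds, summary = summary,
                 best_fraction = best_fraction,
                 probabilities = bind_rows(prob_store),
                 selected = bind_rows(selected_store), k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV; best SNP fraction %.3g\n",
              x$k, x$best_fraction))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  tibble(k = x$k, best_fraction = x$best_fraction,
         n_models = length(unique(x$folds$model)))
}

#' Unweighted ensemble of per-model case probabilities
#'
#' @param prob_table Tibble/data frame: one column per model, one row per
#'   individual (probabilities in (0, 1)).
#' @param threshold Classification threshold (default 0.5).
#' @return An `ensemble_result`: the input columns plus `ensemble` (the
#'   mean) and `class`.
#' @export
ensemble_predict <- function(prob_table, threshold = 0.5) {
  P <- as.matrix(prob_table)
  if (anyNA(P)) ta_stop("missing model probability")
  out <- as_tibble(prob_table)
  out$ensemble <- rowMeans(P)
  out$class <- as.integer(out$ensemble > threshold)
  structure(list(table = out, threshold = threshold),
            class = "ensemble_result")
}

#' Tune the posterior-probability classification threshold
#'
#' Grid search over `seq(step, 1 - step, by = step)` maximizing accuracy;
#' ties break toward 0.5 first, then toward the smaller threshold. A
#' degenerate optimum at the grid boundary is flagged.
#'
#' @param probabilities Predicted case probabilities.
#' @param labels 0/1 labels (both classes present).
#' @param step Grid step (default 0.01).
#' @param metric `"accuracy"`, `"balanced_accuracy"` or `"youden"`.
#' @return List of class `threshold_fit`: `threshold`, `metric_value`,
#'   `degenerate`.
#' @export
tune_threshold <- function(probabilities, labels, step = 0.01,
                           metric = c("accuracy", "balanced_accuracy",
                                      "youden")) {
  metric <- match.arg(metric)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) ta_stop("need both classes")
  grid <- seq(step, 1 - step, by = step)
  score <- vapply(grid, function(t) {
    pred <- as.integer(probabilities > t)
    sens <- mean(pred[labels == 1] == 1)
    spec <- mean(pred[labels == 0] == 0)
    switch(metric,
           accuracy = mean(pred == labels),
           balanced_accuracy = (sens + spec) / 2,
           youden = sens + spec - 1)
  }, numeric(1))
  best <- which(score == max(score))
  best <- best[order(abs(grid[best] - 0.5), grid[best])][1]
  pred_best <- as.integer(probabilities > grid[best])
  structure(list(threshold = grid[best], metric = metric,
                 metric_value = score[best],
                 degenerate = length(unique(pred_best)) == 1L),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> t = %.2f (%s = %.3f)%s\n", x$threshold,
              x$metric, x$metric_value,
              if (x$degenerate) " [degenerate: boundary optimum]" else ""))
  invisible(x)
}
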