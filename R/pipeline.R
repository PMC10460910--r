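#' Write / read a three-column pedigree text file
#'
#' Tab-separated `id`, `sire`, `dam`; unknown parents written as 0.
#'
#' @param ped A `pedigree` tibble.
#' @param path Output file.
#' @export
write_pedigree_file <- function(ped, path) {
  df <- data.frame(id = ped$id,
                   sire = ifelse(is.na(ped$sire), 0L, ped$sire),
                   dam = ifelse(is.na(ped$dam), 0L, ped$dam))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_file
#' @export
read_pedigree_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  ped <- tibble(id = df$id,
                sire = ifelse(df$sire %in% c(0, NA), NA_integer_,
                              as.integer(df$sire)),
                dam = ifelse(df$dam %in% c(0, NA), NA_integer_,
                             as.integer(df$dam)))
  founder <- is.na(ped$sire) & is.na(ped$dam)
  gen <- integer(nrow(ped))
  # generation = 1 + max parent generation (ids assumed parents-first)
  for (i in which(!founder)) {
    gp <- c(gen[match(ped$sire[i], ped$id)], gen[match(ped$dam[i], ped$id)])
    gen[i] <- max(gp, na.rm = TRUE) + 1L
  }
  ped$sex <- NA_integer_
  ped$generation <- gen
  class(ped) <- c("pedigree", class(ped))
  ped
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_individuals = 300L, n_snps = 2000L,
                    n_chromosomes = 2L, ld_rho = 0.9, h2 = 0.4,
                    prevalence = 0.44, n_qtl = 20L, sex_effect = 0.3),
    qc = list(maf_min = 0.05, snp_call_min = 0.95, sample_call_min = 0.90,
              hwe_alpha = 1e-6),
    gwas = list(n_perm = 50L, alpha = 0.05),
    windows = list(window_snps = 90L, top_fraction = 0.05),
    selection = list(cutoff = 1e-4, pi_window_bp = 1e5,
                     h12_window_snps = 20L),
    prs = list(models = c("BRR", "LASSO"), fraction = 0.01,
               n_iter = 2000L, burnin = 500L, thin = 5L),
    evaluate = list(k = 5L),
    stages = c("simulate", "qc", "kinship", "gwas", "windows",
               "selection", "prs", "evaluate")
  )
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains the stages in dependency order — simulate, QC, kinship/PCA,
#' GWAS with permutation threshold, regional window heritability scan,
#' selection-signature scan, Bayesian PRS, cross-validated evaluation —
#' writing every table as TSV plus a JSON run manifest into `out_dir`.
#' Stage toggles, parameters and the global seed come from `config`
#' (missing entries fall back to the defaults; per-stage seeds are derived
#' deterministically from the global seed).
#'
#' @param config Named list (merged over the defaults) or a path to a YAML
#'   file.
#' @param out_dir Output directory (created; default a tempdir run folder).
#' @return Invisibly, a list with every stage's in-memory result and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    ta_stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  out_dir <- out_dir %||% file.path(tempdir(),
                                    paste0("traitarch_run_",
                                           format(Sys.time(), "%Y%m%d%H%M%S")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res <- list(out_dir = out_dir, config = cfg)
  stage_on <- function(s) s %in% cfg$stages

  sc <- sim_config(
    n_individuals = cfg$simulate$n_individuals,
    n_snps = cfg$simulate$n_snps,
    n_chromosomes = cfg$simulate$n_chromosomes,
    ld_rho = cfg$simulate$ld_rho, h2_liability = cfg$simulate$h2,
    prevalence = cfg$simulate$prevalence, n_qtl = cfg$simulate$n_qtl,
    sex_effect = cfg$simulate$sex_effect,
    seed = derive_seed(cfg$seed, "simulate")
  )
  cohort <- simulate_cohort(sc)
  res$cohort <- cohort
  tsv(cohort$genotypes$variants, "variants")
  write_ground_truth(cohort$phenotypes,
                     file.path(out_dir, "ground_truth.json"),
                     seed = sc$seed)
  geno <- cohort$genotypes
  y <- cohort$phenotypes$phenotype
  sex <- cbind(sex = cohort$phenotypes$sex)

  if (stage_on("qc")) {
    qc <- qc_filter(geno, maf_min = cfg$qc$maf_min,
                    snp_call_min = cfg$qc$snp_call_min,
                    sample_call_min = cfg$qc$sample_call_min,
                    hwe_alpha = cfg$qc$hwe_alpha)
    geno <- qc$genotypes
    res$qc <- qc$report
    tsv(tidy(qc$report), "qc_report")
  }
  if (stage_on("kinship")) {
    grm <- grm_vanraden(geno)
    res$grm <- grm
    res$pca <- pca_from_grm(grm, k = 5)
    tsv(res$pca$scores, "pca_scores")
  } else {
    grm <- grm_vanraden(geno)
  }
  if (stage_on("gwas")) {
    nullf <- fit_null_lmm(y, sex, grm)
    scan <- gwas_scan(geno, nullf)
    perm <- permutation_threshold(geno, y, sex, grm,
                                  n_perm = cfg$gwas$n_perm,
                                  seed = derive_seed(cfg$seed, "perm"))
    res$gwas <- scan
    res$thresholds <- list(
      bonferroni = bonferroni_threshold(cfg$gwas$alpha, ncol(geno$values)),
      permutation = perm$threshold
    )
    tsv(as_tibble(scan), "gwas_scan")
    jsonlite::write_json(res$thresholds,
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (stage_on("windows")) {
    win <- make_windows(geno$variants, cfg$windows$window_snps)
    wscan <- scan_windows(geno, y, sex, win,
                          top_fraction = cfg$windows$top_fraction)
    res$windows <- wscan
    tsv(as_tibble(wscan), "window_scan")
  }
  if (stage_on("selection")) {
    sel <- selection_scan(cohort$case_haplotypes, cohort$control_haplotypes,
                          cutoff = cfg$selection$cutoff,
                          pi_window_bp = cfg$selection$pi_window_bp,
                          h12_window_snps = cfg$selection$h12_window_snps,
                          seed = derive_seed(cfg$seed, "mcd"))
    res$selection <- sel
    tsv(sel$case, "selection_case")
    tsv(sel$control, "selection_control")
  }
  if (stage_on("prs") && stage_on("gwas")) {
    sel_idx <- select_top_snps(res$gwas, cfg$prs$fraction)
    Xs <- geno$values[, sel_idx, drop = FALSE]
    colnames(Xs) <- geno$variants$id[sel_idx]
    spec <- bayes_model_spec("BRR", n_iter = cfg$prs$n_iter,
                             burnin = cfg$prs$burnin, thin = cfg$prs$thin,
                             seed = derive_seed(cfg$seed, "prs"))
    fit <- fit_bayes_probit(Xs, y, covariates = sex, spec = spec)
    res$prs <- fit
    pred <- predict_prs(fit, Xs, covariates = sex)
    tsv(bind_cols(tibble(id = geno$samples$id, phenotype = y), pred),
        "prs_predictions")
  }
  if (stage_on("evaluate")) {
    cv <- crossvalidate_models(
      geno, y, covariates = sex, models = cfg$prs$models,
      k = cfg$evaluate$k, fraction_grid = cfg$prs$fraction,
      mcmc = list(n_iter = cfg$prs$n_iter, burnin = cfg$prs$burnin,
                  thin = cfg$prs$thin),
      seed = derive_seed(cfg$seed, "cv")
    )
    res$evaluation <- cv
    tsv(cv$summary, "cv_summary")
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = cfg$seed, stages = cfg$stages,
         config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = "")))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE
  )
  invisible(res)
}
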