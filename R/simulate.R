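#' Simulation configuration for a synthetic case/control cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort and
#' marker panel size, the first-order Markov linkage-disequilibrium
#' parameter, the liability-threshold trait model (heritability, prevalence,
#' number of QTLs, a sex effect on the liability), and an optional localized
#' selective sweep in one group's haplotypes.
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_snps Total number of biallelic SNPs across all chromosomes.
#' @param n_chromosomes Number of chromosomes the SNPs are split across.
#' @param ld_rho Adjacent-marker copy probability of the Markov haplotype
#'   model, in `[0, 1)`. Higher values give slower LD decay.
#' @param maf_range Length-2 numeric, the (low, high) range the per-marker
#'   allele-1 frequencies are drawn from; both ends in `(0, 0.5]`.
#' @param h2_liability Target narrow-sense heritability on the liability
#'   scale, in `[0, 1)`.
#' @param prevalence Population prevalence K of the binary trait, in (0, 1).
#' @param n_qtl Number of causal SNPs.
#' @param sex_effect Additive shift of the liability for sex == 1.
#' @param sweep Optional list with elements `chromosome`, `position`,
#'   `fraction` (of focal-group haplotypes carrying the fixed core
#'   haplotype), and `core_length` (markers).
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_individuals = 183L, n_snps = 2000L,
                       n_chromosomes = 2L, ld_rho = 0.9,
                       maf_range = c(0.05, 0.5), h2_liability = 0.3,
                       prevalence = 0.44, n_qtl = 20L, sex_effect = 0,
                       sweep = NULL, seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals", min = 2L)
  n_snps <- check_count(n_snps, "n_snps", min = 1L)
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1L)
  check_fraction(ld_rho, "ld_rho", 0, 1, hi_open = TRUE)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2]) {
    ta_stop("`maf_range` must be (low, high) with low <= high")
  }
  check_fraction(maf_range[1], "maf_range[low]", 0, 0.5, lo_open = TRUE)
  check_fraction(maf_range[2], "maf_range[high]", 0, 0.5, lo_open = TRUE)
  check_fraction(h2_liability, "h2_liability", 0, 1, hi_open = TRUE)
  check_fraction(prevalence, "prevalence", 0, 1, lo_open = TRUE, hi_open = TRUE)
  n_qtl <- check_count(n_qtl, "n_qtl", min = 0L)
  if (n_qtl > n_snps) ta_stop("`n_qtl` cannot exceed `n_snps`")
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep),
              all(c("chromosome", "position", "fraction", "core_length")
                  %in% names(sweep)))
    check_fraction(sweep$fraction, "sweep$fraction", 0, 1, lo_open = TRUE)
  }
  structure(
    list(n_individuals = n_individuals, n_snps = n_snps,
         n_chromosomes = n_chromosomes, ld_rho = ld_rho,
         maf_range = as.numeric(maf_range), h2_liability = h2_liability,
         prevalence = prevalence, n_qtl = n_qtl, sex_effect = sex_effect,
         sweep = sweep, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a multi-generation pedigree
#'
#' Founders form generation 0; each later generation is produced by random
#' sire x dam matings drawn within the previous generation only. Sex is
#' assigned at birth with probability 1/2, and the number of matings per
#' generation is the number of male/female pairs available. Rows are ordered
#' so that parents always precede their offspring.
#'
#' @param n_founders Number of founder individuals (>= 2).
#' @param n_generations Number of non-founder generations to simulate.
#' @param offspring_per_mating Offspring produced by each mating.
#' @param seed RNG seed.
#' @param max_total If non-`NULL`, stop adding offspring once the pedigree
#'   reaches this many individuals (the final generation is truncated).
#'
#' @return A tibble of class `pedigree` with columns `id`, `sire`, `dam`
#'   (`NA` for unknown parents), `sex` (0 female / 1 male) and `generation`.
#' @export
simulate_pedigree <- function(n_founders, n_generations = 3L,
                              offspring_per_mating = 2L, seed = 1L,
                              max_total = NULL) {
  n_founders <- check_count(n_founders, "n_founders", min = 2L)
  n_generations <- check_count(n_generations, "n_generations", min = 1L)
  offspring_per_mating <- check_count(offspring_per_mating,
                                      "offspring_per_mating", min = 1L)
  set.seed(seed)
  sex <- rbinom(n_founders, 1L, 0.5)
  # guarantee at least one breeding pair among the founders
  if (all(sex == sex[1])) sex[1] <- 1L - sex[1]
  ped <- tibble(
    id = seq_len(n_founders), sire = NA_integer_, dam = NA_integer_,
    sex = sex, generation = 0L
  )
  next_id <- n_founders + 1L
  for (g in seq_len(n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$id[prev$sex == 1L]
    males <- males[sample.int(length(males))]
    females <- prev$id[prev$sex == 0L]
    females <- females[sample.int(length(females))]
    n_mat <- min(length(males), length(females))
    if (n_mat == 0L) break
    kids <- vector("list", n_mat)
    done <- FALSE
    for (m in seq_len(n_mat)) {
      n_off <- offspring_per_mating
      if (!is.null(max_total)) {
        room <- max_total - (next_id - 1L)
        if (room <= 0L) { done <- TRUE; break }
        n_off <- min(n_off, room)
      }
      ids <- next_id + seq_len(n_off) - 1L
      kids[[m]] <- tibble(
        id = ids, sire = rep(males[m], n_off), dam = rep(females[m], n_off),
        sex = rbinom(n_off, 1L, 0.5), generation = g
      )
      next_id <- next_id + n_off
    }
    ped <- bind_rows(ped, bind_rows(kids))
    if (done) break
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Simulate phased haplotypes under a first-order Markov LD model
#'
#' Each chromosome receives an equal share of the SNP panel. Per-marker
#' allele-1 frequencies are drawn uniformly from `maf_range`. Along a
#' haplotype, the allele at marker j copies the allele at marker j-1 with
#' probability `ld_rho` and is otherwise drawn fresh at marker j's
#' frequency, giving geometrically decaying LD. Physical positions are
#' cumulative random gaps of 3-8 kb (about 190 SNPs/Mb).
#'
#' @param config A [sim_config()].
#' @return An object of class `haplotype_set`: a list with `matrix`
#'   (2n x m binary, rows 2i-1 and 2i are individual i's two haplotypes),
#'   `positions`, `chromosome` (per-marker labels), `freq` (the drawn
#'   allele-1 frequencies) and `group`.
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_hap <- 2L * config$n_individuals
  m <- config$n_snps
  chr_sizes <- diff(floor(seq(0, m, length.out = config$n_chromosomes + 1L)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), chr_sizes)
  freq <- runif(m, config$maf_range[1], config$maf_range[2])
  positions <- unlist(lapply(chr_sizes, function(sz) {
    cumsum(sample(3000:8000, sz, replace = TRUE))
  }), use.names = FALSE)
  H <- matrix(0L, nrow = n_hap, ncol = m)
  start <- 0L
  for (sz in chr_sizes) {
    idx <- start + seq_len(sz)
    H[, idx[1]] <- rbinom(n_hap, 1L, freq[idx[1]])
    for (j in idx[-1]) {
      copy <- rbinom(n_hap, 1L, config$ld_rho) == 1L
      fresh <- rbinom(n_hap, 1L, freq[j])
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    }
    start <- start + sz
  }
  structure(
    list(matrix = H, positions = positions, chromosome = chrom,
         freq = freq, group = "all"),
    class = "haplotype_set"
  )
}

#' Collapse a haplotype set to additive genotype dosages
#'
#' @param haps A `haplotype_set`.
#' @param sample_ids Optional sample id vector (default `ind_1..n`).
#' @return A `genotype_matrix` whose values are the row-pair sums of the
#'   haplotype matrix (exact by construction).
#' @export
haplotypes_to_genotypes <- function(haps, sample_ids = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  H <- haps$matrix
  n <- nrow(H) / 2L
  G <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  ids <- sample_ids %||% paste0("ind_", seq_len(n))
  rownames(G) <- ids
  variants <- tibble(
    chrom = haps$chromosome,
    pos = haps$positions,
    id = paste0("snp_", seq_len(ncol(G))),
    ref = "A", alt = "B",
    maf = pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
  )
  genotype_matrix(G, variants, tibble(id = ids))
}

#' Simulate a liability-threshold binary phenotype
#'
#' The liability is `genetic value + sex_effect * sex + e` with
#' `e ~ Normal(0, 1 - h2)`. In genotype mode the genetic value is a sum of
#' QTL dosage effects, drawn Normal(0,1) and jointly rescaled so the
#' realized genetic variance equals `h2` exactly; in pedigree mode breeding
#' values flow down the pedigree (parental average plus Mendelian sampling)
#' and are rescaled the same way. The threshold is the empirical
#' `(1 - K)` quantile of the realized liabilities, so the case count is
#' `round(K * n)` by construction.
#'
#' @param x A `genotype_matrix` or a `pedigree`.
#' @param h2 Liability-scale heritability in `[0, 1)`.
#' @param K Prevalence in (0, 1).
#' @param n_qtl Number of causal SNPs (genotype mode only).
#' @param sex_effect Liability shift for sex == 1.
#' @param seed RNG seed.
#' @param sex Optional 0/1 vector; defaults to Bernoulli(1/2) draws
#'   (pedigree mode uses the pedigree's own sex column).
#'
#' @return A list of class `sim_phenotypes`: `liability`, `phenotype` (0/1),
#'   `sex`, `threshold`, `true_qtl` (tibble of snp index + effect, genotype
#'   mode), `genetic_value`, `true_h2`.
#' @export
simulate_liability_phenotypes <- function(x, h2, K, n_qtl = 20L,
                                          sex_effect = 0, seed = 1L,
                                          sex = NULL) {
  check_fraction(h2, "h2", 0, 1, hi_open = TRUE)
  check_fraction(K, "K", 0, 1, lo_open = TRUE, hi_open = TRUE)
  set.seed(seed)
  true_qtl <- NULL
  if (inherits(x, "genotype_matrix")) {
    n <- nrow(x$values)
    n_qtl <- check_count(n_qtl, "n_qtl", min = 0L)
    if (n_qtl > ncol(x$values)) ta_stop("`n_qtl` exceeds the SNP count")
    if (h2 > 0 && n_qtl > 0L) {
      qtl_idx <- sort(sample.int(ncol(x$values), n_qtl))
      eff <- rnorm(n_qtl)
      gv_raw <- as.numeric(scale(x$values[, qtl_idx, drop = FALSE],
                                 scale = FALSE) %*% eff)
      s <- sqrt(h2 / var(gv_raw))
      gv <- gv_raw * s
      true_qtl <- tibble(snp = qtl_idx, effect = eff * s)
    } else {
      gv <- numeric(n)
      true_qtl <- tibble(snp = integer(), effect = numeric())
    }
  } else if (inherits(x, "pedigree")) {
    n <- nrow(x)
    if (h2 > 0) {
      bv <- numeric(n)
      founder <- is.na(x$sire) & is.na(x$dam)
      bv[founder] <- rnorm(sum(founder), 0, sqrt(h2))
      ord <- order(x$generation, x$id)
      for (i in ord[!founder[ord]]) {
        bv[i] <- 0.5 * (bv[match(x$sire[i], x$id)] +
                          bv[match(x$dam[i], x$id)]) +
          rnorm(1, 0, sqrt(h2 / 2))
      }
      gv <- bv - mean(bv)
      gv <- gv * sqrt(h2 / var(gv))
    } else {
      gv <- numeric(n)
    }
    if (is.null(sex)) sex <- x$sex
  } else {
    ta_stop("`x` must be a genotype_matrix or a pedigree")
  }
  if (is.null(sex)) sex <- rbinom(n, 1L, 0.5)
  liab <- gv + sex_effect * sex + rnorm(n, 0, sqrt(1 - h2))
  n_cases <- round(K * n)
  if (n_cases < 1L || n_cases >= n) {
    ta_stop("prevalence K leaves no cases or no controls at this n")
  }
  gamma <- sort(liab)[n - n_cases]
  structure(
    list(liability = liab, phenotype = as.integer(liab > gamma), sex = sex,
         threshold = gamma, true_qtl = true_qtl, genetic_value = gv,
         true_h2 = h2),
    class = "sim_phenotypes"
  )
}

#' Overwrite a core window with a fixed donor haplotype (hard/soft sweep)
#'
#' A fraction `f` of haplotype rows (chosen at random) have the
#' `core_length` markers centred on `position` replaced by the first
#' haplotype's core segment; every other site is untouched. `f = 0` returns
#' the input unchanged.
#'
#' @param haps A `haplotype_set`.
#' @param position Physical position (bp) of the sweep centre.
#' @param f Fraction of haplotypes carrying the swept core, in (0, 1].
#' @param core_length Core window length in markers.
#' @param chromosome Chromosome label the sweep sits on (default: the
#'   chromosome containing `position` if unique).
#' @param seed RNG seed for carrier selection.
#' @return The modified `haplotype_set`, with a `sweep_core` attribute
#'   giving the affected column indices.
#' @export
apply_sweep <- function(haps, position, f, core_length,
                        chromosome = NULL, seed = 1L) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (f == 0) return(haps)
  check_fraction(f, "f", 0, 1, lo_open = TRUE)
  core_length <- check_count(core_length, "core_length", min = 1L)
  chromosome <- chromosome %||% haps$chromosome[1]
  on_chr <- which(haps$chromosome == chromosome)
  if (length(on_chr) == 0L) ta_stop("unknown chromosome")
  centre <- on_chr[which.min(abs(haps$positions[on_chr] - position))]
  half <- core_length %/% 2L
  core <- (centre - half):(centre - half + core_length - 1L)
  if (core[1] < min(on_chr) || core[length(core)] > max(on_chr)) {
    ta_stop("sweep core window extends beyond the chromosome")
  }
  set.seed(seed)
  n_hap <- nrow(haps$matrix)
  carriers <- sample.int(n_hap, ceiling(f * n_hap))
  donor <- haps$matrix[1L, core]
  haps$matrix[carriers, core] <- matrix(donor, nrow = length(carriers),
                                        ncol = core_length, byrow = TRUE)
  attr(haps, "sweep_core") <- core
  haps
}

#' Simulate a complete case/control cohort with known ground truth
#'
#' Runs the full generator: Markov haplotypes, genotypes as haplotype
#' row-pair sums, a liability-threshold phenotype with a sex covariate, and
#' (if configured) a selective sweep applied to the case group's haplotypes
#' after phenotype assignment.
#'
#' @param config A [sim_config()].
#' @param pedigree Optional `pedigree` to attach (not used for the genetic
#'   values; genotype mode drives the phenotype).
#' @return A list of class `sim_cohort` with `genotypes`, `haplotypes`,
#'   `case_haplotypes`, `control_haplotypes`, `phenotypes`
#'   (a `sim_phenotypes`), `config`, and `pedigree`.
#' @export
simulate_cohort <- function(config, pedigree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  haps <- simulate_haplotypes(config)
  geno <- haplotypes_to_genotypes(haps)
  phen <- simulate_liability_phenotypes(
    geno, h2 = config$h2_liability, K = config$prevalence,
    n_qtl = config$n_qtl, sex_effect = config$sex_effect,
    seed = derive_seed(config$seed, "phenotypes")
  )
  geno$samples$sex <- phen$sex
  geno$samples$phenotype <- phen$phenotype
  hap_rows <- function(ind) sort(c(2L * ind - 1L, 2L * ind))
  split_haps <- function(ind, label) {
    out <- haps
    out$matrix <- haps$matrix[hap_rows(ind), , drop = FALSE]
    out$group <- label
    out
  }
  case_h <- split_haps(which(phen$phenotype == 1L), "case")
  ctrl_h <- split_haps(which(phen$phenotype == 0L), "control")
  if (!is.null(config$sweep)) {
    case_h <- apply_sweep(
      case_h, position = config$sweep$position, f = config$sweep$fraction,
      core_length = config$sweep$core_length,
      chromosome = config$sweep$chromosome,
      seed = derive_seed(config$seed, "sweep")
    )
  }
  structure(
    list(genotypes = geno, haplotypes = haps, case_haplotypes = case_h,
         control_haplotypes = ctrl_h, phenotypes = phen, config = config,
         pedigree = pedigree),
    class = "sim_cohort"
  )
}

#' Write cohort ground truth as a JSON sidecar
#'
#' @param phen A `sim_phenotypes`.
#' @param path Output file.
#' @param seed The generator seed to record.
#' @export
write_ground_truth <- function(phen, path, seed = NA_integer_) {
  stopifnot(inherits(phen, "sim_phenotypes"))
  jsonlite::write_json(
    list(true_h2 = phen$true_h2, threshold = phen$threshold, seed = seed,
         true_qtl = phen$true_qtl),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
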