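---
title: "Models and methods in traitarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in traitarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

traitarch dissects the genetic architecture of a binary (case/control)
trait in a structured animal population: pedigree-based heritability on the
liability scale, mixed-model genome-wide association with empirical
significance thresholds, regional (window) heritability, haplotype-based
selection-signature scanning with a decorrelated composite statistic, and
Bayesian whole-genome probit regression for polygenic risk prediction. This
vignette explains each model, its assumptions, the tunable parameters that
matter, and the numerical and design choices the package makes.

## The liability-threshold view of a binary trait

Throughout the package a binary phenotype $y_i \in \{0, 1\}$ is treated as
the thresholding of a latent normal liability
$l_i = \eta_i + \varepsilon_i$, $\varepsilon_i \sim N(0, 1)$, with
$y_i = 1$ iff $l_i > \gamma$. The residual variance is fixed at 1 (probit
identification) and the threshold at 0, with an intercept absorbing the
prevalence. Heritability on the liability scale is
$h^2 = \sigma^2_g / (\sigma^2_g + 1)$. Some software instead adds a second
unit of "link variance" in the denominator; `fit_probit_animal_model()`
exposes that convention behind `include_link_variance` (default off), and
all of the package's parameter-recovery tests are self-consistent under the
default convention.

## Synthetic cohorts: what the generator emulates, and what it does not

Every statistical claim in the test suite is made against synthetic
cohorts with known ground truth, built by `simulate_cohort()`:

* **Pedigrees** (`simulate_pedigree()`): founders form generation zero;
  each later generation arises from random male x female matings drawn
  within the previous generation only, sex assigned Bernoulli(1/2) at
  birth. An optional `max_total` truncates the last generation, which is
  how the package reproduces the shape of a 688-founder, 1,947-individual,
  multi-generation breeding population.
* **Haplotypes** (`simulate_haplotypes()`): a first-order Markov model
  along each chromosome — the allele at marker $j$ copies marker $j-1$'s
  allele with probability `ld_rho` and is otherwise drawn fresh at that
  marker's frequency. One parameter gives geometrically decaying LD, which
  is all the EHH/iHS/nSL/H12 machinery needs at desk scale; the trade-off
  is that the generator makes no attempt at coalescent realism (no
  recombination hotspots, no allele-frequency spectrum from drift, no
  genotyping error, autosomal-diploid markers only). Passing tests
  therefore demonstrate correctness of the statistics and calibration
  under a known LD process, not performance on any particular real genome.
  Physical positions use random 3–8 kb gaps (about 190 SNPs/Mb, matching
  a dense array on a ~2.4 Gb genome).
* **Phenotypes** (`simulate_liability_phenotypes()`): QTL effects are
  drawn Normal(0,1) and *jointly rescaled so the realized genetic variance
  equals the target `h2` exactly*; this removes sampling noise from
  parameter-recovery tests. The threshold is the empirical $(1-K)$
  quantile, so the case count is `round(K * n)` by construction. Sex is
  independent of genotype and shifts the liability by `sex_effect`.
* **Sweeps** (`apply_sweep()`): a fraction $f$ of haplotypes have a fixed
  core window overwritten by one donor haplotype — a hard sweep for
  $f = 1$, soft-sweep-like for smaller $f$.

The disease prevalence of the emulated breed is not known; `prevalence` is
a free parameter defaulting to 0.44, the case fraction of the emulated
study sample (80 cases / 183 animals).

## Quality control

`qc_filter()` applies, in a fixed documented order: sample call rate
(< 0.90 removed), SNP call rate (< 0.95), minor allele frequency (< 0.05,
recomputed after sample removal), and a Hardy–Weinberg exact test
(p < 1e-6). The order is fixed so each removed SNP is attributed to
exactly one filter and the report's counts always sum. HWE uses the
two-sided conditional exact test (summing heterozygote configurations no
more probable than the observed one) rather than chi-square, because the
desk-scale fixtures have small genotype counts; it is computed on all
samples, cases and controls together. Missing genotypes are imputed per
SNP by expected dosage $2\hat p$ (default) or the modal genotype; expected
dosage produces real-valued codes, and all downstream matrix algebra
accepts real dosages.

## Relationship matrices

The genomic relationship matrix is
$G = XX' / (2\sum_i p_i(1-p_i))$ with $X$ the genotypes centred by twice
the counted-allele frequency. The formula is algebraically invariant to
which allele is counted, so the package always counts the alt allele for
determinism rather than re-identifying the minor allele. The pedigree
numerator relationship matrix uses the tabular method; inbreeding is
$F_j = A_{jj} - 1$. Principal components are eigenvectors of $G$ scaled by
the square root of their eigenvalues, with negative eigenvalues clipped to
zero (and counted) before variance fractions are formed.

## Pedigree heritability: Bayesian probit animal model

`fit_probit_animal_model()` Gibbs-samples
$l = X\beta + u + e$, $u \sim N(0, A\sigma^2_g)$, $e \sim N(0, I)$. Three
implementation choices matter:

1. **Eigenbasis sampling.** With $A = UDU'$ and $u = Uv$, every full
   conditional of $v$ is diagonal, so one iteration costs two
   matrix-vector products instead of a Cholesky factorization.
2. **Collapsed variance update.** The naive conjugate update of
   $\sigma^2_g$ given $v$ mixes pathologically slowly for binary data (the
   chain inherits an initialization transient thousands of iterations
   long). Instead the package draws $\sigma^2_g$ from its *marginal*
   conditional given the liabilities — in the eigenbasis
   $z_i = (U'(l - X\beta))_i \sim N(0, d_i\sigma^2_g + 1)$ independently,
   so the marginal is a cheap one-dimensional target — via two Metropolis
   steps on $\log\sigma^2_g$ (proposal SD 0.4), then draws $v$ exactly.
   This is a partially collapsed Gibbs sampler; first- and second-half
   posterior means agree from short burn-ins.
3. **Prior.** The scaled-inverse-$\chi^2(\nu = 1, S = 0.01)$ default is
   deliberately near-scale-free: with one degree of freedom and a small
   scale the density behaves like $s^{-3/2}$ and keeps mass near zero.
   A unit scale ($S = 1$) may look "weakly informative" but has
   essentially no mass below $\sigma^2_g \approx 0.1$, which forces the
   posterior of a trait with *no* pedigree signal up to $h^2 \approx 0.2$
   — the binary-trait likelihood is weak enough that this matters. Under
   the default, a null trait posterior sits near 0.05 and a trait
   simulated at $h^2 = 0.22$ on a 1,947-individual pedigree is recovered
   within the posterior's own spread.

Default MCMC is 20,000 iterations, 2,000 burn-in, thinning 5 — enough for
the collapsed sampler at these sizes; production-length chains are one
argument away. HPD intervals are shortest windows over the sorted draws
(window length `round(mass * n)`, ties to the smallest lower bound).

## Mixed-model GWAS

The binary phenotype is modelled *linearly* with a GRM random effect; the
null model is fitted once by REML (one eigendecomposition plus a
one-dimensional profile optimization of $\delta = \sigma^2_e/\sigma^2_g$
over $\log_{10}\delta \in [-6, 6]$), and every SNP is tested by
generalized least squares in the whitened space with the null variance
components held fixed — the standard two-stage approximation for
case-control GWAS with relatedness. With an identity GRM the p-values
reduce exactly to least-squares Wald tests using the null residual
variance. Monomorphic SNPs are flagged with effect 0 and p = 1.

Significance is assessed two ways: Bonferroni ($\alpha/m$) and an
empirical genome-wide threshold from 500 phenotype permutations — each
permutation refits the variance components on the cached rotation, reruns
the scan, and records the genome-wide minimum p-value; the threshold is
the 5th percentile (type-7 quantile) of that min-p distribution. The
permutation shuffles the phenotype only, so both genotype-phenotype and
covariate-phenotype associations break. Genomic inflation is
$\lambda = \mathrm{median}(\chi^2_1)/0.4549$. Gene annotation reports any
interval intersecting ±50 kb around a hit (1-based inclusive coordinates;
BED input converted on read).

## Regional window heritability

SNPs are partitioned into consecutive 90-SNP windows per chromosome; a
trailing remainder keeps its own window when it has at least 45 SNPs and
is otherwise merged into the previous window (chromosome ends are the
package's own rule — no published convention exists). For each window a
two-variance-component REML model is fitted: window GRM, rest-of-genome
GRM, and residual, all on the 0/1 phenotype modelled linearly (a
two-component *logistic* REML is nonstandard; the linear screen is common
practice for regional heritability ranking). The rest-of-genome GRM is
obtained by downdating the whole-genome cross-product — subtracting the
window's contribution and rescaling the denominator — which costs
$O(n^2 \cdot 90)$ per window instead of a full rebuild. Components are
maximized directly by box-constrained quasi-Newton iterations on the
restricted likelihood (non-convergence is flagged per window, not
raised). Windows are ranked by local $h^2_w = \sigma^2_w / (\sigma^2_w +
\sigma^2_r + \sigma^2_e)$; the top `floor(0.05 * n_windows)` are flagged
(floor reproduces 238 from 4,769 windows).

## Selection signatures and DCMS

Per group (cases and controls separately, each phased):

* $\pi$ — per-site pairwise diversity, averaged in 100 kb windows
  (left tail: low diversity is selection-like);
* $\Delta\pi$ — windowed control-minus-case diversity from the focal
  group's standpoint (right tail; the sign convention is configurable
  because the original analysis never states one);
* iHS and nSL — log-ratios of ancestral/derived integrated EHH,
  standardized to mean 0 / SD 1 in 20 derived-allele-frequency bins;
  iHS integrates EHH over base pairs (trapezoid), nSL over segregating
  sites; integration truncates where EHH < 0.05, and cores whose EHH never
  reaches the cutoff before a chromosome end are dropped by default
  (`keep_truncated` retains them); absolute values are scored right-tail;
* H12 — $(p_1 + p_2)^2 + \sum_{i\ge3} p_i^2$ over 20-SNP windows
  (right tail), sensitive to hard and soft sweeps.

The "ancestral" allele is the reference (0) allele of the simulated
haplotypes; no outgroup polarization is attempted. Window statistics are
joined per site (each site inherits its window's value) so the composite
is per-site. Each statistic becomes a fractional-rank p-value
$p = 1 - r/(n+1)$ (average ranks for ties, hence p strictly inside (0,1)),
the statistics' correlation matrix is estimated robustly by the minimum
covariance determinant (75% support, 500 random subsets under a fixed
seed; exactly singular inputs fall back to the classical covariance with
a warning), and the decorrelated composite is

$$\mathrm{DCMS}_j = \sum_i \frac{\log((1-p_{ij})/p_{ij})}{\sum_k |r_{ik}|}.$$

DCMS values are fitted to a normal by a Huber M-estimated intercept-only
robust regression (tuning constant 1.345, MAD-initialized scale) and
upper-tail p-values taken from that fit; candidate sites fall at
p ≤ 1e-4. Case-specific genes are those within ±50 kb of case candidates
and absent from the control candidate list. A constant statistic (e.g.
$\Delta\pi$ when the groups coincide) is dropped with a warning rather
than poisoning the correlation matrix.

The default statistic set is $\{\pi, \Delta\pi, \mathrm{nSL},
\mathrm{H12}, \mathrm{iHS}\}$ — five statistics, treating within-group
diversity and between-group diversity contrast as distinct signals — and
is fully configurable.

## Polygenic prediction

`select_top_snps()` takes the `floor(fraction * m)` smallest-p SNPs from a
scan (ties broken by genome position). Four Bayesian probit whole-genome
regressions share one data-augmented Gibbs sampler
(`fit_bayes_probit()`): Bayesian ridge (one shared marker variance),
BayesB (per-marker variances plus a point mass at zero), BayesC (shared
variance plus a point mass), and Bayesian LASSO (per-marker exponential
scale mixing with a Gamma($s = 1.1$, $r$) hyperprior on $\lambda^2$,
$r = (s-1) / (2\,(1-R^2)/R^2 \cdot MS_x)$ at $R^2 = 0.5$). Marker-variance
scales default to the same $R^2 = 0.5$ heuristic: the prior mode of the
total marker variance matches half the (unit) liability variance spread
over $MS_x$, the summed marker dosage variances. The null-mixture
probability $\pi$ gets a Beta(2.5, 2.5) prior (vague, centred at 0.5).
The residual variance is fixed at 1 and the threshold at 0, as in the
animal model; the intercept and the sex covariate are unpenalized.
Predictions are $\hat\eta = \hat\mu + G\hat\beta$ (posterior means) and
case probability $\Phi(\hat\eta)$.

RF, gradient boosting, LASSO and elastic net baselines delegate to
randomForest, xgboost and glmnet, tuned by grid search with internal
stratified 10-fold cross-validation (the elastic net tunes $\alpha$ and
$\lambda$ jointly). The bespoke science is the Bayesian samplers and the
liability-scale evaluation; the baselines are deliberately off-the-shelf.

## Evaluation on the liability scale

Five-fold stratified cross-validation re-runs the *entire* GWAS (GRM, null
REML, scan) inside each training fold before selecting SNPs, so selection
never sees held-out phenotypes — the original workflow may have selected
on the full sample, but that leaks test labels, and the package opts for
statistical validity (a leakage audit with a planted fold-specific
association is part of the test suite). Three accuracies are reported per
model x SNP-fraction x fold: observed-scale $R^2$, and liability-scale
$R^2$ on the probit ($\mathrm{var}(\hat\eta)/(\mathrm{var}(\hat\eta)+1)$)
and logit ($\pi^2/3 = 3.2899$ residual) scales; the Robertson
transformation $R^2_l = R^2_o\,K(1-K)/z^2$ is provided for converting
observed-scale values (at $K = 0.5$ the factor is exactly $\pi/2$). The
logistic residual constant is the standard $\pi^2/3$; printed values of
"3.92" in some sources are a transposition of 3.29. Ensemble prediction is
the unweighted mean of per-model probabilities; the classification
threshold is tuned on a labelled grid (step 0.01) maximizing accuracy,
ties toward 0.5 then toward the smaller threshold, with a degeneracy flag
when the chosen threshold classifies everything into one class.

## Problem sizes used by the test suite

The automated tests exercise every claim at desk scale, chosen so the
whole suite runs on a single CPU: cohorts of 90–500 individuals and
150–1,000 SNPs for module tests; the heritability-recovery check uses the
full emulated pedigree (1,947 individuals, 20,000 Gibbs iterations);
null-calibration suites use 20 replicates at 100–500 individuals; signal
-detection suites use 6–10 replicates. The acceptance script reproduces
the heritability-recovery computation end to end from a single seed.

## Known limitations

* The LD model is first-order Markov; long-range LD, recombination maps
  and demography are out of scope, so empirical detection power on real
  genomes will differ from the synthetic calibration.
* The GWAS and window models treat the binary phenotype linearly; no
  penalized-quasi-likelihood logistic mixed model is provided.
* Genotype imputation is marginal (expected dosage), not haplotype-aware.
* X-chromosome dosage is not special-cased; all simulated markers are
  autosomal.
* Multi-allelic variants raise an error on read rather than being split.
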