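#' Simulation configuration for a synthetic biobank cohort
#'
#' Describes every parameter of the cohort generator: cohort size, genome
#' layout, linkage-disequilibrium (LD) block structure, subpopulation
#' differentiation, the liability model for case status, confounding between
#' subpopulation and both disease risk and allele frequency, quality-control
#' artifact rates, and the random seed. A config plus its seed fully
#' determines the generated cohort.
#'
#' @param n_samples Number of participants.
#' @param n_chromosomes Number of chromosomes, labelled `1..n_chromosomes`.
#' @param variants_per_chromosome Variants simulated per chromosome. Zero is
#'   allowed and yields a covariates-only cohort (no genotypes).
#' @param chromosome_length_bp Chromosome length in base pairs; variant
#'   positions are drawn uniformly without replacement from `1..length`.
#' @param block_size Number of consecutive variants per LD block.
#' @param within_block_rho Adjacent-variant correlation of the latent AR(1)
#'   Gaussian used to induce LD within a block; must lie in `[0, 1)`.
#' @param n_subpops Number of discrete subpopulations.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`; 0 gives
#'   no differentiation.
#' @param base_maf_range Interval within `[0.001, 0.5]` from which shared base
#'   allele frequencies are drawn uniformly.
#' @param prevalence_intercept Liability-scale (log-odds) intercept of the
#'   disease model.
#' @param causal_effects `NULL` or a data.frame with columns `chrom`,
#'   `rank` (1-based variant index within the chromosome), `beta` (per-allele
#'   log-odds), and optionally `maf` to pin the base allele frequency of the
#'   planted variant.
#' @param covariate_effect_sizes Named numeric vector of log-odds effects on
#'   disease for `age` (per SD of age) and/or `chip` (effect of the second
#'   chip relative to the first).
#' @param confounding_strength Log-odds effect of the (centred, unit-scaled)
#'   subpopulation score on disease risk, coupling subpopulation to both risk
#'   and allele frequency.
#' @param artifact_rates Named proportions for `sex_mismatch`, `aneuploidy`,
#'   `missingness_outlier`, `het_outlier`.
#' @param info_beta_params Length-2 shape vector for per-variant imputation
#'   INFO draws from a Beta distribution.
#' @param missing_rate Per-entry probability that a dosage is missing
#'   (missing completely at random).
#' @param female_frac Fraction of participants simulated as genetically
#'   female (they are never cases and are removed by sample QC for a
#'   male-only phenotype).
#' @param pcs_from_genotypes If `TRUE` (default) the 10 principal components
#'   are computed from the centred dosage matrix (thinned to at most
#'   `pca_max_variants` variants); if `FALSE`, or when no genotypes exist,
#'   PCs are simulated from the true subpopulation score plus noise.
#' @param pca_max_variants Maximum number of (evenly thinned) variants used
#'   for the PC computation.
#' @param exact_counts `NULL`, or `c(cases, controls)` to assign exactly that
#'   many cases among eligible males by risk-weighted sampling without
#'   replacement (used by the count-exact preset).
#' @param seed Integer seed; fully determines the cohort.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples,
                       n_chromosomes = 4,
                       variants_per_chromosome = 5000,
                       chromosome_length_bp = 50e6,
                       block_size = 25,
                       within_block_rho = 0.8,
                       n_subpops = 2,
                       fst = 0.05,
                       base_maf_range = c(0.01, 0.5),
                       prevalence_intercept = qlogis(0.07),
                       causal_effects = NULL,
                       covariate_effect_sizes = c(age = 0),
                       confounding_strength = 0,
                       artifact_rates = c(sex_mismatch = 0, aneuploidy = 0,
                                          missingness_outlier = 0,
                                          het_outlier = 0),
                       info_beta_params = c(20, 1.2),
                       missing_rate = 0,
                       female_frac = 0.5,
                       pcs_from_genotypes = TRUE,
                       pca_max_variants = 400,
                       exact_counts = NULL,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    variants_per_chromosome = as.integer(variants_per_chromosome),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    block_size = as.integer(block_size),
    within_block_rho = as.numeric(within_block_rho),
    n_subpops = as.integer(n_subpops),
    fst = as.numeric(fst),
    base_maf_range = as.numeric(base_maf_range),
    prevalence_intercept = as.numeric(prevalence_intercept),
    causal_effects = causal_effects,
    covariate_effect_sizes = covariate_effect_sizes,
    confounding_strength = as.numeric(confounding_strength),
    artifact_rates = artifact_rates,
    info_beta_params = as.numeric(info_beta_params),
    missing_rate = as.numeric(missing_rate),
    female_frac = as.numeric(female_frac),
    pcs_from_genotypes = isTRUE(pcs_from_genotypes),
    pca_max_variants = as.integer(pca_max_variants),
    exact_counts = exact_counts,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(is_count(cfg$n_samples) && cfg$n_samples >= 1,
              "n_samples must be a positive count")
  assert_that(is_count(cfg$n_chromosomes) && cfg$n_chromosomes >= 1,
              "n_chromosomes must be a positive count")
  assert_that(is_count(cfg$variants_per_chromosome),
              "variants_per_chromosome must be a non-negative count")
  if (cfg$variants_per_chromosome > 0) {
    assert_that(cfg$block_size >= 1 &&
                cfg$variants_per_chromosome >= cfg$block_size,
                "need variants_per_chromosome >= block_size >= 1")
    assert_that(cfg$variants_per_chromosome <= cfg$chromosome_length_bp,
                "more variants than base-pair positions on a chromosome")
  }
  assert_that(cfg$within_block_rho >= 0 && cfg$within_block_rho < 1,
              "within_block_rho must lie in [0, 1); rho >= 1 is rejected")
  assert_that(cfg$fst >= 0 && cfg$fst < 1, "fst must lie in [0, 1)")
  assert_that(length(cfg$base_maf_range) == 2 &&
              cfg$base_maf_range[1] >= 0.001 &&
              cfg$base_maf_range[2] <= 0.5 &&
              cfg$base_maf_range[1] <= cfg$base_maf_range[2],
              "base_maf_range must be an interval within [0.001, 0.5]")
  assert_that(is_prop(cfg$missing_rate), "missing_rate must be in [0, 1]")
  assert_that(is_prop(cfg$female_frac), "female_frac must be in [0, 1]")
  for (nm in names(cfg$artifact_rates)) {
    assert_that(is_prop(cfg$artifact_rates[[nm]]),
                paste0("artifact rate '", nm, "' must be in [0, 1]"))
  }
  assert_that(length(cfg$info_beta_params) == 2 &&
              all(cfg$info_beta_params > 0),
              "info_beta_params must be two positive shapes")
  if (!is.null(cfg$causal_effects)) {
    ce <- cfg$causal_effects
    assert_that(is.data.frame(ce) && all(c("chrom", "rank", "beta") %in%
                names(ce)), "causal_effects needs columns chrom, rank, beta")
    assert_that(!anyDuplicated(ce[, c("chrom", "rank")]),
                "causal positions must be unique")
    assert_that(all(ce$chrom >= 1 & ce$chrom <= cfg$n_chromosomes),
                "causal chrom outside simulated chromosomes")
    assert_that(all(ce$rank >= 1 & ce$rank <= cfg$variants_per_chromosome),
                "causal rank outside variants_per_chromosome")
  }
  if (!is.null(cfg$exact_counts)) {
    assert_that(length(cfg$exact_counts) == 2 && all(cfg$exact_counts >= 0),
                "exact_counts must be c(cases, controls)")
  }
  invisible(cfg)
}

#' Named simulation presets
#'
#' Ready-made configurations for the study conditions exercised throughout
#' the package:
#' \describe{
#'   \item{desk}{The full desk-scale default: 4 chromosomes of 5,000 variants
#'     and 25,000 participants with confounded subpopulation structure.}
#'   \item{null}{A calibration cohort with no genetic, covariate, or
#'     confounding effects (case prevalence 7 percent), used to check type-I
#'     error and genomic-control lambda.}
#'   \item{confounded}{A male-only cohort with two differentiated
#'     subpopulations whose membership raises disease risk, planted causal
#'     variants spanning weak to strong effects, and genotype-derived PCs.
#'     Case fraction is close to the 6.8 percent of the motivating biobank
#'     male pool.}
#'   \item{planted}{A small cohort with three strongly associated planted
#'     variants (per-allele OR 2.0 at 30 percent frequency) for locus
#'     recovery checks.}
#'   \item{biobank-counts}{A covariates-only cohort with exactly 15,250 cases
#'     and 208,128 eligible male controls for count-exact design checks.}
#' }
#'
#' @param name One of `"desk"`, `"null"`, `"confounded"`, `"planted"`,
#'   `"biobank-counts"`.
#' @param seed Integer seed stored in the config.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("desk", "null", "confounded", "planted",
                                "biobank-counts"),
                       seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    desk = list(
      n_samples = 25000L, n_chromosomes = 4L,
      variants_per_chromosome = 5000L,
      block_size = 25L, within_block_rho = 0.8,
      n_subpops = 2L, fst = 0.05,
      base_maf_range = c(0.01, 0.5),
      prevalence_intercept = qlogis(0.05),
      causal_effects = data.frame(
        chrom = c(1L, 2L, 3L, 4L),
        rank = c(1200L, 2600L, 900L, 4100L),
        beta = log(c(2.0, 1.8, 1.6, 1.5)),
        maf = c(0.30, 0.25, 0.30, 0.35)),
      covariate_effect_sizes = c(age = 0.35),
      confounding_strength = 1.0,
      artifact_rates = c(sex_mismatch = 0.005, aneuploidy = 0.002,
                         missingness_outlier = 0.005, het_outlier = 0.005),
      missing_rate = 0.01, female_frac = 0.5),
    null = list(
      n_samples = 4000L, n_chromosomes = 4L,
      variants_per_chromosome = 5000L,
      block_size = 1L, within_block_rho = 0,
      n_subpops = 1L, fst = 0,
      base_maf_range = c(0.05, 0.5),
      prevalence_intercept = qlogis(0.07),
      causal_effects = NULL,
      covariate_effect_sizes = c(age = 0),
      confounding_strength = 0,
      artifact_rates = c(sex_mismatch = 0, aneuploidy = 0,
                         missingness_outlier = 0, het_outlier = 0),
      missing_rate = 0, female_frac = 0),
    confounded = list(
      n_samples = 6000L, n_chromosomes = 4L,
      variants_per_chromosome = 1000L,
      block_size = 20L, within_block_rho = 0.7,
      n_subpops = 2L, fst = 0.05,
      base_maf_range = c(0.02, 0.5),
      prevalence_intercept = -3.4,
      causal_effects = data.frame(
        chrom = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
        rank = c(150L, 420L, 700L, 300L, 550L, 850L,
                 200L, 480L, 760L, 150L, 500L, 800L),
        beta = log(c(2.2, 1.65, 1.55, 2.0, 1.40, 1.60,
                     1.8, 1.45, 1.60, 1.55, 1.62, 1.40)),
        maf = c(0.30, 0.30, 0.25, 0.25, 0.35, 0.30,
                0.30, 0.35, 0.25, 0.30, 0.25, 0.30)),
      covariate_effect_sizes = c(age = 0.35),
      confounding_strength = 1.0,
      artifact_rates = c(sex_mismatch = 0.005, aneuploidy = 0.002,
                         missingness_outlier = 0.005, het_outlier = 0.005),
      missing_rate = 0.01, female_frac = 0,
      pca_max_variants = 300L),
    planted = list(
      n_samples = 6000L, n_chromosomes = 2L,
      variants_per_chromosome = 800L,
      block_size = 20L, within_block_rho = 0.7,
      n_subpops = 2L, fst = 0.02,
      base_maf_range = c(0.02, 0.5),
      prevalence_intercept = qlogis(0.065),
      causal_effects = data.frame(
        chrom = c(1L, 1L, 2L),
        rank = c(200L, 620L, 400L),
        beta = log(c(2.0, 2.0, 2.0)),
        maf = c(0.30, 0.30, 0.30)),
      covariate_effect_sizes = c(age = 0),
      confounding_strength = 0,
      artifact_rates = c(sex_mismatch = 0, aneuploidy = 0,
                         missingness_outlier = 0, het_outlier = 0),
      missing_rate = 0.005, female_frac = 0),
    `biobank-counts` = list(
      n_samples = 223378L, n_chromosomes = 1L,
      variants_per_chromosome = 0L,
      n_subpops = 2L, fst = 0.05,
      prevalence_intercept = qlogis(0.068),
      covariate_effect_sizes = c(age = 0.5),
      confounding_strength = 0.5,
      artifact_rates = c(sex_mismatch = 0, aneuploidy = 0,
                         missingness_outlier = 0, het_outlier = 0),
      missing_rate = 0, female_frac = 0,
      pcs_from_genotypes = FALSE,
      exact_counts = c(cases = 15250L, controls = 208128L))
  )
  args$seed <- seed
  dots <- list(...)
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]   # whole-value override
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d (female fraction %.2f)\n",
              x$n_samples, x$female_frac))
  cat(sprintf("  genome: %d chromosome(s) x %d variants, blocks of %d, rho %.2f\n",
              x$n_chromosomes, x$variants_per_chromosome, x$block_size,
              x$within_block_rho))
  cat(sprintf("  structure: %d subpopulation(s), Fst %.3f, confounding %.2f\n",
              x$n_subpops, x$fst, x$confounding_strength))
  cat(sprintf("  causal variants: %d; seed: %d\n",
              if (is.null(x$causal_effects)) 0L else nrow(x$causal_effects),
              x$seed))
  invisible(x)
}
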