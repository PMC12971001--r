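test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(100, within_block_rho = 1), "rho")
  expect_error(sim_config(100, fst = 1), "fst")
  expect_error(sim_config(100, variants_per_chromosome = 5, block_size = 10),
               "block_size")
  expect_error(sim_config(100, causal_effects = data.frame(
    chrom = c(1, 1), rank = c(3, 3), beta = c(0.1, 0.2))), "unique")
  expect_s3_class(sim_config(100, fst = 0), "sim_config")
})

test_that("subpopulation differentiation recovers the target Fst", {
  cfg <- sim_config(n_samples = 800, n_chromosomes = 1,
                    variants_per_chromosome = 2000, block_size = 1,
                    within_block_rho = 0, n_subpops = 2, fst = 0.05,
                    base_maf_range = c(0.1, 0.5), missing_rate = 0,
                    female_frac = 0, seed = 42)
  subpop <- rep(1:2, each = 400)
  g <- simulate_genotypes(cfg, subpop)
  p1 <- colMeans(g$dosages[subpop == 1, ]) / 2
  p2 <- colMeans(g$dosages[subpop == 2, ]) / 2
  fst_hat <- hudson_fst(p1, p2, 800, 800)
  expect_gt(fst_hat, 0.04)
  expect_lt(fst_hat, 0.06)

  # no-differentiation limit: frequencies agree across subpops and with the
  # shared base frequency within binomial sampling error
  cfg0 <- sim_config(n_samples = 2000, n_chromosomes = 1,
                     variants_per_chromosome = 300, block_size = 1,
                     within_block_rho = 0, n_subpops = 2, fst = 0,
                     base_maf_range = c(0.1, 0.5), missing_rate = 0,
                     female_frac = 0, seed = 7)
  sp0 <- rep(1:2, each = 1000)
  g0 <- simulate_genotypes(cfg0, sp0)
  phat <- colMeans(g0$dosages) / 2
  p0 <- g0$variants$base_freq
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / (2 * 2000))
  expect_lt(mean(abs(z) > 3.5), 0.01)
  expect_lt(abs(hudson_fst(colMeans(g0$dosages[sp0 == 1, ]) / 2,
                           colMeans(g0$dosages[sp0 == 2, ]) / 2,
                           2000, 2000)), 0.005)
})

test_that("LD blocks follow the latent AR(1) and vanish at block size one", {
  base <- list(n_samples = 10000, n_chromosomes = 1,
               variants_per_chromosome = 60, n_subpops = 1, fst = 0,
               base_maf_range = c(0.2, 0.5), missing_rate = 0,
               female_frac = 0, seed = 3)
  adj_cor <- function(block_size, rho) {
    cfg <- do.call(sim_config, c(base, list(block_size = block_size,
                                            within_block_rho = rho)))
    g <- simulate_genotypes(cfg, rep(1L, 10000))
    cc <- cor(g$dosages)
    # mean |r| over within-block adjacent pairs
    idx <- seq_len(ncol(cc) - 1)
    keep <- (idx %% block_size) != 0
    mean(abs(cc[cbind(idx, idx + 1)][if (block_size == 1) TRUE else keep]))
  }
  expect_lt(adj_cor(1, 0.8), 0.05)
  r <- vapply(c(0.2, 0.5, 0.8), function(rho) adj_cor(10, rho), 0)
  expect_true(all(diff(r) > 0))       # monotone in rho
  expect_gt(r[3], 0.4)
})

test_that("liability model hits the intercept prevalence and plants signal", {
  cfg <- sim_config(n_samples = 20000, n_chromosomes = 1,
                    variants_per_chromosome = 10, block_size = 1,
                    within_block_rho = 0, n_subpops = 1, fst = 0,
                    prevalence_intercept = qlogis(0.07),
                    missing_rate = 0, female_frac = 0, seed = 5)
  ch <- simulate_cohort(cfg)
  frac <- mean(ch$samples$case_status == "case")
  expect_lt(abs(frac - 0.07), 3 * sqrt(0.07 * 0.93 / 20000) + 0.002)

  # planted per-allele effect shows up in a single-variant logistic fit
  cfg2 <- sim_config(n_samples = 8000, n_chromosomes = 1,
                     variants_per_chromosome = 10, block_size = 1,
                     within_block_rho = 0, n_subpops = 1, fst = 0,
                     prevalence_intercept = qlogis(0.2),
                     causal_effects = data.frame(chrom = 1, rank = 5,
                                                 beta = log(1.5), maf = 0.3),
                     missing_rate = 0, female_frac = 0, seed = 6)
  ch2 <- simulate_cohort(cfg2)
  y <- as.numeric(ch2$samples$case_status == "case")
  d <- ch2$dosages[, 5]
  fit <- glm(y ~ d, family = binomial)
  z <- coef(summary(fit))["d", "z value"]
  expect_gt(z, 4)
  expect_lt(abs(coef(fit)["d"] - log(1.5)), 0.15)

  # confounding couples subpopulation to case status
  cfg3 <- sim_config(n_samples = 6000, n_chromosomes = 1,
                     variants_per_chromosome = 10, block_size = 1,
                     within_block_rho = 0, n_subpops = 2, fst = 0.05,
                     confounding_strength = 1,
                     missing_rate = 0, female_frac = 0, seed = 8)
  ch3 <- simulate_cohort(cfg3)
  tab <- table(ch3$truth$subpop, ch3$samples$case_status == "case")
  expect_lt(chisq.test(tab)$p.value, 1e-6)
})

test_that("artifact injection matches configured rates and the INFO law", {
  cfg <- sim_config(n_samples = 10000, n_chromosomes = 1,
                    variants_per_chromosome = 2000, block_size = 1,
                    within_block_rho = 0, n_subpops = 1, fst = 0,
                    artifact_rates = c(sex_mismatch = 0.01, aneuploidy = 0.005,
                                       missingness_outlier = 0.01,
                                       het_outlier = 0.01),
                    info_beta_params = c(20, 1.2),
                    missing_rate = 0, female_frac = 0.5, seed = 12)
  ch <- simulate_cohort(cfg)
  n_mm <- sum(ch$samples$reported_sex != ch$samples$genetic_sex)
  expect_lt(abs(n_mm - 100), 4 * sqrt(100))
  fr_info <- mean(ch$variants$info < 0.7)
  expect_lt(abs(fr_info - pbeta(0.7, 20, 1.2)), 0.02)

  # all-zero rates leave the cohort unflagged
  cfg0 <- sim_config(n_samples = 500, n_chromosomes = 1,
                     variants_per_chromosome = 20, block_size = 1,
                     within_block_rho = 0, n_subpops = 1, fst = 0,
                     missing_rate = 0, female_frac = 0, seed = 13)
  ch0 <- simulate_cohort(cfg0)
  expect_identical(ch0$samples$reported_sex, ch0$samples$genetic_sex)
  expect_false(any(ch0$samples$aneuploidy_flag))
})

test_that("cohort serialization round-trips and rejects truncated input", {
  cfg <- sim_config(n_samples = 50, n_chromosomes = 2,
                    variants_per_chromosome = 30, block_size = 5,
                    within_block_rho = 0.5, n_subpops = 2, fst = 0.05,
                    missing_rate = 0.05, female_frac = 0.3, seed = 21)
  ch <- simulate_cohort(cfg)
  expect_gt(sum(is.na(ch$dosages)), 0)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$samples$sample_id, ch$samples$sample_id)
  expect_equal(back$samples$case_status, ch$samples$case_status)
  expect_equal(back$samples$age, ch$samples$age)
  expect_equal(back$samples$PC3, ch$samples$PC3)
  expect_equal(back$variants$pos, ch$variants$pos)
  expect_equal(back$variants$is_causal, ch$variants$is_causal)
  expect_equal(unname(back$dosages), unname(ch$dosages))  # NA preserved
  expect_equal(back$truth$subpop, ch$truth$subpop)
  expect_equal(back$truth$config$seed, cfg$seed)

  # truncated dosage matrix is a dimension-mismatch error
  dlines <- readLines(file.path(dir, "dosages.tsv"))
  writeLines(dlines[1:20], file.path(dir, "dosages.tsv"))
  expect_error(read_cohort(dir), "dimension mismatch")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_samples = 120, n_chromosomes = 1,
                    variants_per_chromosome = 40, block_size = 5,
                    within_block_rho = 0.6, n_subpops = 2, fst = 0.05,
                    confounding_strength = 0.5, missing_rate = 0.02,
                    female_frac = 0.4, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$dosages, b$dosages)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
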