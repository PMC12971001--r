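test_that("logistic fits reduce to closed forms and match a Newton oracle", {
  # intercept-only: coefficient is the sample logit
  y <- rep(c(1, 0), c(30, 70))
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(y, X)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.3), tolerance = 1e-8)

  # 2x2 table: beta is the table's log odds ratio, SE the root summed
  # reciprocal cells
  tab <- c(a = 20, b = 80, c = 10, d = 90)  # exposed/unexposed x case/ctrl
  y2 <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  x2 <- c(rep(1, 100), rep(0, 100))
  X2 <- cbind("(Intercept)" = 1, exposure = x2)
  fit2 <- fit_logistic(y2, X2, tol = 1e-12)
  lor <- log(20 * 90 / (80 * 10))
  se <- sqrt(sum(1 / tab))
  expect_equal(unname(fit2$coefficients["exposure"]), lor, tolerance = 1e-7)
  expect_equal(sqrt(fit2$vcov["exposure", "exposure"]), se,
               tolerance = 1e-7)

  # random small datasets: agreement with an independent Newton solver
  set.seed(17)
  for (trial in 1:5) {
    n <- 120
    Xr <- cbind("(Intercept)" = 1, a = rnorm(n), b = rnorm(n),
                c = rbinom(n, 1, 0.4))
    yr <- rbinom(n, 1, plogis(0.3 + 0.5 * Xr[, "a"] - 0.7 * Xr[, "c"]))
    f1 <- fit_logistic(yr, Xr)
    f2 <- newton_logistic(yr, Xr)
    expect_equal(unname(f1$coefficients), unname(f2$coefficients),
                 tolerance = 1e-8)
    expect_equal(unname(sqrt(diag(f1$vcov))),
                 unname(sqrt(diag(f2$vcov))), tolerance = 1e-6)
  }
})

test_that("the per-variant scan equals direct refits and handles exclusions", {
  cfg <- sim_config(n_samples = 600, n_chromosomes = 1,
                    variants_per_chromosome = 40, block_size = 5,
                    within_block_rho = 0.5, n_subpops = 2, fst = 0.05,
                    prevalence_intercept = qlogis(0.3),
                    confounding_strength = 0.5,
                    missing_rate = 0.02, female_frac = 0, seed = 44)
  ch <- simulate_cohort(cfg)
  pools <- eligible_pools(ch)
  design <- select_all(pools$cases, pools$pool)
  fv <- filter_variants(ch$variants, ch$dosages,
                        c(design$cases, design$controls))
  st <- run_gwas(ch, design, fv$variants)
  expect_identical(st$ID, st$ID[order(st$CHROM, st$GENPOS)])

  ids <- c(design$cases, design$controls)
  smp <- ch$samples[match(ids, ch$samples$sample_id), ]
  yy <- as.numeric(smp$case_status == "case")
  X0 <- ctrlgwas:::build_design_matrix(smp, default_covariates())
  for (vid in sample(st$ID, 8)) {
    d <- ch$dosages[match(ids, rownames(ch$dosages)), vid]
    obs <- !is.na(d)
    oracle <- newton_logistic(yy[obs], cbind(X0[obs, ], DOSAGE = d[obs]))
    i <- match(vid, st$ID)
    expect_equal(st$BETA[i], unname(oracle$coefficients["DOSAGE"]),
                 tolerance = 1e-6)
    expect_equal(st$SE[i], unname(sqrt(oracle$vcov["DOSAGE", "DOSAGE"])),
                 tolerance = 1e-6)
    expect_equal(st$N[i], sum(obs))
    expect_equal(st$A1FREQ[i], mean(d[obs]) / 2)
  }
  # log10p consistency with the chi-square, and no underflow at extremes
  expect_equal(st$LOG10P,
               -log10(pchisq(st$CHISQ, 1, lower.tail = FALSE)),
               tolerance = 1e-10)
  # finite far beyond double-precision p-value underflow (p ~ 1e-436)
  expect_gt(ctrlgwas:::chisq_to_log10p(2000), 400)
  expect_lt(ctrlgwas:::chisq_to_log10p(2000), 450)
  expect_true(is.finite(ctrlgwas:::chisq_to_log10p(5000)))

  # constant-dosage variant is excluded with its reason
  ch2 <- ch
  ch2$dosages[, 3] <- 2
  st2 <- run_gwas(ch2, design, fv$variants)
  expect_false(ch$variants$variant_id[3] %in% st2$ID)
  expect_equal(unname(attr(st2, "excluded")[["zero variance"]]), 1)
})

test_that("genomic lambda has its null law, fixed point, and scaling", {
  expect_equal(genomic_lambda(rep(qchisq(0.5, 1), 200)), 1)
  x <- withr::with_seed(9, rchisq(10000, 1))
  lam <- genomic_lambda(x)
  expect_lt(abs(lam - 1), 0.03)
  expect_equal(genomic_lambda(2 * x), 2 * lam)
  expect_error(genomic_lambda(rchisq(50, 1)), "100")
})

test_that("summary statistics survive a TSV round trip with metadata", {
  st <- make_stats(c(1L, 1L, 2L), c(100, 200, 300), c(3.2, 8.1, 1.0))
  attr(st, "strategy") <- "random"
  attr(st, "seed") <- 42L
  attr(st, "n_cases") <- 10L
  attr(st, "n_controls") <- 40L
  class(st) <- c("gwas_stats", "data.frame")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(st, path)
  expect_true(startsWith(readLines(path, n = 1), "##strategy=random"))
  back <- read_sumstats(path)
  expect_equal(back$LOG10P, st$LOG10P)
  expect_equal(attr(back, "strategy"), "random")
  expect_equal(attr(back, "n_controls"), 40L)
  # plain REGENIE-like file without metadata is accepted too
  plain <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(as.data.frame(st), plain, sep = "\t")
  expect_equal(read_sumstats(plain)$CHISQ, st$CHISQ)
})
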