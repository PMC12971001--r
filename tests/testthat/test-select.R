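test_that("all-controls and random designs have the stated shapes", {
  cases <- sprintf("c%02d", 1:5)
  pool <- sprintf("p%02d", 1:30)
  da <- select_all(cases, pool)
  expect_equal(length(da$controls), 30)
  expect_error(select_all(cases, character(0)), "empty")

  dr <- select_random(cases, pool, ratio_k = 4, seed = 42)
  expect_equal(length(dr$controls), 20)
  expect_false(any(duplicated(dr$controls)))
  expect_false(any(dr$controls %in% cases))
  # seeded reproducibility; different seeds diverge
  dr2 <- select_random(cases, pool, 4, 42)
  expect_identical(sort(dr$controls), sort(dr2$controls))
  dr3 <- select_random(cases, pool, 4, 43)
  expect_false(identical(sort(dr$controls), sort(dr3$controls)))
  # pool of exactly k * n_cases is taken whole; smaller errors
  d_all <- select_random(cases, pool[1:20], 4, 1)
  expect_setequal(d_all$controls, pool[1:20])
  expect_error(select_random(cases, pool[1:19], 4, 1), "19 available")
  # caller RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(select_random(cases, pool, 4, 99))
  expect_identical(before, .Random.seed)
})

test_that("propensity scores reduce to the known closed forms", {
  s <- make_samples(2000, n_cases = 400)
  # covariates independent of status: scores concentrate at the case rate
  sc <- estimate_propensity(s, c("age", "PC1", "PC2"))
  expect_lt(abs(mean(sc) - 0.2), 0.01)
  expect_lt(sd(sc), 0.05)

  # single binary covariate: scores equal the stratum case rates
  s2 <- make_samples(500, n_cases = 100)
  s2$grp <- rep(c("x", "y"), length.out = 500)
  sc2 <- estimate_propensity(s2, "grp")
  for (g in c("x", "y")) {
    rate <- mean(s2$case_status[s2$grp == g] == "case")
    expect_lt(max(abs(sc2[s2$grp == g] - rate)), 1e-6)
  }

  # perfect separation is reported as an actionable error
  s3 <- make_samples(200, n_cases = 50)
  s3$leak <- as.numeric(s3$case_status == "case")
  expect_error(estimate_propensity(s3, "leak"), "separation")
})

test_that("nearest-neighbour matching reproduces an independent greedy oracle", {
  set.seed(31)
  for (trial in 1:25) {
    n_case <- sample(3:8, 1)
    n_pool <- sample(20:40, 1)
    k <- sample(1:3, 1)
    cs <- runif(n_case)
    ps <- runif(n_pool)
    cases <- sprintf("c%02d", seq_len(n_case))
    pool <- sprintf("p%02d", seq_len(n_pool))
    scores <- setNames(c(cs, ps), c(cases, pool))
    got <- match_nearest(cases, pool, scores,
                         selection_config("matched", ratio_k = k))
    oracle <- greedy_match_oracle(cs, ps, k)
    for (ci in seq_len(n_case)) {
      expect_identical(got$pairing[[cases[ci]]], pool[oracle[[ci]]])
    }
    expect_equal(length(got$controls), k * n_case)
    expect_false(any(duplicated(got$controls)))
  }
})

test_that("matching handles duplicates, determinism, and short pools", {
  # each case surrounded by its own exact score duplicates
  cases <- c("cA", "cB")
  pool <- sprintf("p%d", 1:8)
  scores <- setNames(c(0.2, 0.8, rep(0.2, 4), rep(0.8, 4)),
                     c(cases, pool))
  d <- match_nearest(cases, pool, scores, selection_config("matched"))
  expect_setequal(d$pairing$cA, paste0("p", 1:4))
  expect_setequal(d$pairing$cB, paste0("p", 5:8))
  # no RNG involved: repeated calls identical under different ambient seeds
  set.seed(1); d1 <- match_nearest(cases, pool, scores,
                                   selection_config("matched"))
  set.seed(999); d2 <- match_nearest(cases, pool, scores,
                                     selection_config("matched"))
  expect_identical(d1$pairing, d2$pairing)
  # exact distance ties resolve to the smaller pool index
  scores2 <- setNames(c(0.5, 0.4, 0.6, 0.4, 0.6),
                      c("c1", "q1", "q2", "q3", "q4"))
  d3 <- match_nearest("c1", c("q1", "q2", "q3", "q4"), scores2,
                      selection_config("matched", ratio_k = 2))
  expect_identical(d3$pairing$c1, c("q1", "q2"))
  # insufficient pool: error unless partial matching is allowed
  expect_error(match_nearest(cases, pool[1:7], scores,
                             selection_config("matched")), "too small")
  dp <- match_nearest(cases, pool[1:7], scores,
                      selection_config("matched", allow_partial = TRUE))
  expect_equal(length(dp$controls), 7)
})

test_that("balance diagnostics match hand-computed SMD and favour matching", {
  s <- make_samples(6, n_cases = 3)
  s$age <- c(50, 60, 70, 40, 50, 60)
  d <- new_design_for_test(s)
  bal <- balance_diagnostics(d, s, covariates = "age")
  smd_hand <- (mean(c(50, 60, 70)) - mean(c(40, 50, 60))) /
    sqrt((var(c(50, 60, 70)) + var(c(40, 50, 60))) / 2)
  expect_equal(bal$smd_after, smd_hand, tolerance = 1e-12)
  expect_equal(bal$smd_before, smd_hand, tolerance = 1e-12)
  expect_equal(bal$eqq_mean, 10, tolerance = 1e-12)

  # identical distributions give SMD zero
  s2 <- make_samples(40, n_cases = 20)
  s2$age <- rep(c(45, 55), 20)
  d2 <- new_design_for_test(s2)
  b2 <- balance_diagnostics(d2, s2, covariates = "age")
  expect_equal(b2$smd_after, 0, tolerance = 1e-12)

  # confounded cohort: matching beats random selection on mean |SMD|
  cfg <- sim_preset("confounded", seed = 2, n_samples = 3000L,
                    variants_per_chromosome = 150L, pca_max_variants = 150L,
                    causal_effects = data.frame(chrom = 1L, rank = 75L,
                                                beta = log(2), maf = 0.3))
  ch <- simulate_cohort(cfg)
  pools <- eligible_pools(ch)
  sc <- estimate_propensity(pools$samples)
  dm <- match_nearest(pools$cases, pools$pool, sc,
                      selection_config("matched"))
  dr <- select_random(pools$cases, pools$pool, 4, 42)
  bm <- balance_diagnostics(dm, pools$samples)
  br <- balance_diagnostics(dr, pools$samples)
  expect_lt(mean(abs(bm$smd_after)), mean(abs(br$smd_after)))
  # and reduces imbalance relative to the unmatched pool by a clear margin
  expect_lt(mean(abs(bm$smd_after)), 0.8 * mean(abs(bm$smd_before)))
})
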