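test_that("locus matching pairs runs as expected and is count-optimal", {
  a <- make_loci(c(1L, 1L, 2L), c(1e6, 5e6, 2e6))
  # identical inputs: everything pairs, nothing unique
  mm <- match_loci(a, a)
  expect_equal(nrow(mm$pairs), 3L)
  expect_length(mm$unique_a, 0)
  # leads 600 kb apart with a 500 kb window stay unique
  b <- make_loci(1L, 1e6 + 6e5)
  mm2 <- match_loci(a, b)
  expect_equal(nrow(mm2$pairs), 0L)
  expect_length(mm2$unique_b, 1)
  # symmetry of the pair count
  set.seed(23)
  for (trial in 1:40) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    la <- make_loci(sample(1:2, na, TRUE), sample.int(8e6, na),
                    sprintf("a%d", 1:na))
    lb <- make_loci(sample(1:2, nb, TRUE), sample.int(8e6, nb),
                    sprintf("b%d", 1:nb))
    n_ab <- nrow(match_loci(la, lb)$pairs)
    expect_equal(n_ab, nrow(match_loci(lb, la)$pairs))
    # pair count equals the brute-force optimum
    expect_equal(n_ab, max_pairs_bruteforce(la$LEAD_POS, la$CHROM,
                                            lb$LEAD_POS, lb$CHROM, 5e5))
  }
})

test_that("three-way Venn regions count signal clusters conservatively", {
  a <- make_loci(1L, c(1e6, 10e6, 20e6, 30e6, 40e6, 50e6),
                 sprintf("A%d", 1:6))
  # identical runs: everything in the triple intersection
  v <- venn_three(a, a, a)
  expect_equal(unname(v$loci[["ABC"]]), 6L)
  expect_equal(v$loci_union, 6L)
  expect_equal(unname(v$leads[["ABC"]]), 6L)
  # disjoint runs populate only unique regions
  b <- make_loci(1L, c(100e6, 110e6), sprintf("B%d", 1:2))
  c3 <- make_loci(2L, c(1e6, 10e6, 20e6), sprintf("C%d", 1:3))
  v2 <- venn_three(a, b, c3)
  expect_equal(unname(v2$loci[c("A", "B", "C")]), c(6L, 2L, 3L))
  expect_equal(sum(v2$loci[c("AB", "AC", "BC", "ABC")]), 0L)
  expect_equal(v2$loci_union, 11L)
  # constructed overlap design: 3 in all runs, 2 shared A-B only,
  # 1 shared A-C only, plus singletons
  la <- make_loci(1L, c(1e6, 10e6, 20e6, 30e6, 40e6, 50e6, 60e6),
                  sprintf("A%d", 1:7))
  lb <- make_loci(1L, c(1e6, 10e6, 20e6, 30.1e6, 40.1e6, 80e6),
                  c("A1", "A2", "sharedb3", "b4", "b5", "B6"))
  lc <- make_loci(1L, c(1e6, 10e6, 20e6, 50.1e6, 90e6),
                  c("A1", "A2", "sharedc3", "c4", "C5"))
  v3 <- venn_three(la, lb, lc)
  expect_equal(unname(v3$loci[["ABC"]]), 3L)
  expect_equal(unname(v3$loci[["AB"]]), 2L)
  expect_equal(unname(v3$loci[["AC"]]), 1L)
  expect_equal(unname(v3$loci[["BC"]]), 0L)
  expect_equal(unname(v3$loci[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_equal(v3$loci_union, 9L)
  # lead Venn is exact-ID based
  expect_equal(unname(v3$leads[["ABC"]]), 2L)  # A1, A2
  expect_equal(v3$leads_union, length(unique(c(la$LEAD_ID, lb$LEAD_ID,
                                               lc$LEAD_ID))))
})

test_that("dosage r-squared matches the hand value and its invariances", {
  dos <- cbind(v1 = c(0, 1, 2, 2), v2 = c(0, 1, 1, 2),
               v3 = c(0, 0, 0, 0))
  rownames(dos) <- paste0("s", 1:4)
  expect_equal(ld_r2(dos, "v1", "v1"), 1)
  expect_equal(as.numeric(ld_r2(dos, "v1", "v2")), 8 / 11,
               tolerance = 1e-12)
  # affine recoding leaves r2 unchanged
  dos2 <- dos; dos2[, "v2"] <- 3 - 2 * dos2[, "v2"]
  expect_equal(as.numeric(ld_r2(dos2, "v1", "v2")), 8 / 11,
               tolerance = 1e-12)
  # zero variance is flagged, not silently zero
  r <- ld_r2(dos, "v1", "v3")
  expect_true(is.na(r))
  expect_identical(attr(r, "flag"), "zero variance")
  # independent variants at large n decorrelate
  set.seed(6)
  big <- cbind(x = rbinom(10000, 2, 0.3), y = rbinom(10000, 2, 0.3))
  rownames(big) <- sprintf("i%05d", 1:10000)
  expect_lt(as.numeric(ld_r2(big, "x", "y")), 0.01)
})

test_that("LD consistency reproduces the printed-count percentages", {
  fx <- make_ld_fixture(n_discordant = 19, n_high = 11)
  res <- ld_consistency(fx$run, fx$ref, fx$dosages)
  expect_equal(res$n_discordant, 19L)
  expect_equal(res$n_high_ld, 11L)
  expect_equal(res$percentage, 57.89)
  fx2 <- make_ld_fixture(n_discordant = 13, n_high = 11)
  res2 <- ld_consistency(fx2$run, fx2$ref, fx2$dosages)
  expect_equal(res2$percentage, 84.62)
  # no discordant leads: not applicable rather than zero
  same <- fx$ref
  res3 <- ld_consistency(same, fx$ref, fx$dosages)
  expect_equal(res3$n_discordant, 0L)
  expect_true(is.na(res3$percentage))
})

test_that("effect concordance recovers slopes, harmonization, and R2", {
  bm <- data.frame(id = sprintf("s%d", 1:10), chrom = 1L,
                   pos = (1:10) * 1e6, effect_allele = "G",
                   beta = seq(-0.2, 0.25, length.out = 10))
  st <- data.frame(CHROM = 1L, GENPOS = (1:10) * 1e6,
                   ID = sprintf("s%d", 1:10), ALLELE0 = "A", ALLELE1 = "G",
                   BETA = seq(-0.2, 0.25, length.out = 10))
  res <- suppressWarnings(effect_concordance(st, bm))  # exact fit
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_equal(res$adj_r_squared, 1, tolerance = 1e-12)
  # allele swap flips the sign and is harmonized away
  st2 <- st
  st2$ALLELE0 <- "G"; st2$ALLELE1 <- "A"; st2$BETA <- -st2$BETA
  res2 <- suppressWarnings(effect_concordance(st2, bm))
  expect_equal(res2$slope, res$slope, tolerance = 1e-12)
  expect_equal(res2$adj_r_squared, res$adj_r_squared, tolerance = 1e-12)
  # mismatching allele pairs are dropped and counted
  st3 <- st
  st3$ALLELE0[1] <- "T"; st3$ALLELE1[1] <- "C"
  res3 <- suppressWarnings(effect_concordance(st3, bm))
  expect_equal(res3$n_matched, 9L)
  expect_equal(res3$n_dropped, 1L)
  expect_error(effect_concordance(st[1:2, ], bm[1:2, ]), "3")
  # synthetic pair with known population R2
  pair <- simulate_benchmark_pair(n = 269, r2 = 0.82, seed = 5)
  res4 <- effect_concordance(pair$stats, pair$benchmark)
  expect_equal(res4$n_matched, 269L)
  expect_lt(abs(res4$adj_r_squared - 0.82), 0.05)
  # benchmark TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(pair$benchmark, path)
  expect_equal(read_benchmark(path), pair$benchmark)
})
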