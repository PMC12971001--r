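#' Analytic power for the case-control additive allelic test
#'
#' Normal approximation for the per-allele log odds ratio: with control
#' risk-allele frequency p0 and per-allele odds ratio OR, the case allele
#' frequency is p1 = OR q0 / (1 + OR q0) with q0 = p0 / (1 - p0); the
#' variance of the log-OR estimate is
#' V = 1 / (2 n_cases p1 (1 - p1)) + 1 / (2 n_controls p0 (1 - p0)),
#' and two-sided power at level alpha is
#' Phi(|ln OR| / sqrt(V) - z) + Phi(-|ln OR| / sqrt(V) - z) with
#' z = z(1 - alpha / 2). At OR = 1 the power equals alpha.
#'
#' @param n_cases,n_controls Case and control counts.
#' @param maf Control-population risk-allele frequency in (0, 0.5].
#' @param odds_ratio Per-allele odds ratio (> 0).
#' @param alpha Two-sided significance level (default genome-wide 5e-8).
#' @return Power in `[0, 1]` (vectorized over `maf` and `odds_ratio`).
#' @export
analytic_power <- function(n_cases, n_controls, maf, odds_ratio,
                           alpha = 5e-8) {
  assert_that(all(n_cases > 0) && all(n_controls > 0),
              "sample sizes must be positive")
  assert_that(all(maf > 0) && all(maf < 1),
              "maf must lie in (0, 1); it is the risk-allele frequency, typically the minor allele (<= 0.5)")
  assert_that(all(odds_ratio > 0), "odds_ratio must be positive")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  p0 <- maf
  q0 <- p0 / (1 - p0)
  p1 <- odds_ratio * q0 / (1 + odds_ratio * q0)
  V <- 1 / (2 * n_cases * p1 * (1 - p1)) +
    1 / (2 * n_controls * p0 * (1 - p0))
  z <- qnorm(1 - alpha / 2)
  ncp <- abs(log(odds_ratio)) / sqrt(V)
  pnorm(ncp - z) + pnorm(-ncp - z)
}

#' Power curve over a MAF x OR grid
#'
#' Applies [analytic_power()] over the grid with
#' `n_controls = ratio_k * n_cases` and returns a plot-ready long table.
#'
#' @param n_cases Number of cases.
#' @param ratio_k Controls per case.
#' @param maf_grid Vector of allele frequencies.
#' @param or_list Vector of odds ratios.
#' @param alpha Two-sided significance level.
#' @return Data.frame with columns MAF, OR, POWER.
#' @export
power_curve <- function(n_cases, ratio_k = 4L, maf_grid, or_list,
                        alpha = 5e-8) {
  assert_that(length(maf_grid) > 0 && length(or_list) > 0,
              "maf_grid and or_list must be non-empty")
  grid <- expand.grid(MAF = maf_grid, OR = or_list,
                      KEEP.OUT.ATTRS = FALSE)
  grid$POWER <- analytic_power(n_cases, ratio_k * n_cases,
                               grid$MAF, grid$OR, alpha)
  grid
}

#' Empirical power by Monte-Carlo simulation of the allelic Wald test
#'
#' Simulates case and control risk-allele counts binomially at the
#' frequencies implied by `maf` and `odds_ratio`, forms the 2x2 allele
#' table, and applies the Wald test of the log odds ratio
#' (SE = sqrt of the summed reciprocal cells, Haldane 0.5 correction when a
#' cell is empty). Serves as the independent simulation benchmark for
#' [analytic_power()].
#'
#' @inheritParams analytic_power
#' @param n_reps Number of simulated tests (default 2000).
#' @param seed Seed (RNG state is restored afterwards).
#' @return Rejection fraction.
#' @export
simulate_power <- function(n_cases, n_controls, maf, odds_ratio,
                           alpha = 5e-8, n_reps = 2000L, seed = 1L) {
  p0 <- maf
  q0 <- p0 / (1 - p0)
  p1 <- odds_ratio * q0 / (1 + odds_ratio * q0)
  crit <- qchisq(1 - alpha, df = 1)
  with_seed(seed, {
    a <- rbinom(n_reps, 2 * n_cases, p1)       # case risk alleles
    b <- 2 * n_cases - a
    c_ <- rbinom(n_reps, 2 * n_controls, p0)   # control risk alleles
    d <- 2 * n_controls - c_
    zero <- a == 0 | b == 0 | c_ == 0 | d == 0
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    c_[zero] <- c_[zero] + 0.5; d[zero] <- d[zero] + 0.5
    lor <- log(a) - log(b) - log(c_) + log(d)
    se2 <- 1 / a + 1 / b + 1 / c_ + 1 / d
    mean(lor^2 / se2 > crit)
  })
}

#' Compute-cost reduction from a smaller design
#'
#' `100 * (1 - (n_sub / n_full)^exponent)`, rounded to the nearest integer
#' percent: the reduction in computing resource usage when an algorithm of
#' complexity O(N^exponent) runs on `n_sub` instead of `n_full` samples.
#'
#' @param n_full Full-design sample count.
#' @param n_sub Reduced-design sample count.
#' @param complexity_exponent Algorithmic complexity exponent (>= 1;
#'   1 = linear, 2 = quadratic).
#' @return Integer percent reduction.
#' @export
resource_reduction <- function(n_full, n_sub, complexity_exponent = 1) {
  assert_that(n_sub > 0 && n_sub <= n_full,
              "need 0 < n_sub <= n_full")
  assert_that(complexity_exponent >= 1, "complexity_exponent must be >= 1")
  round(100 * (1 - (n_sub / n_full)^complexity_exponent))
}
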