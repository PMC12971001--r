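# ctrlgwas

Evaluating control-selection strategies for biobank-scale case-control GWAS.

## The problem

When a biobank phenotype has 15,000 cases and 200,000+ eligible controls,
the analyst can run the association scan against **all** controls, a seeded
**random** 1:k subset, or a propensity-score **matched** 1:k subset. The
choice moves three things at once: statistical power, compute cost (linear
or worse in sample size), and robustness to residual population
stratification. `ctrlgwas` implements all three designs end to end on
simulated cohorts with known truth, so their consequences — genomic
inflation, locus yield, lead-SNP stability, power, cost — can be measured.

The core quantities:

- **Design construction.** Random selection draws exactly `k * n_cases`
  controls without replacement under a fixed seed. Matching fits a logistic
  propensity model `P(case | age, centre, chip, PC1..PC10)` and pairs each
  case with its k nearest available controls by score (greedy, without
  replacement, deterministic tie-breaking).
- **Association model.** Per variant, logistic regression
  `logit P(case) = b0 + b_g * dosage + covariates`, Wald chi-square on
  `b_g`, p-values in log space (`LOG10P`).
- **Genomic control.** `lambda = median(chisq) / 0.4549` over the scan.
- **Loci.** Variants with `p < 5e-8` are chained into loci whenever
  consecutive gaps are <= 500 kb; the lead SNP is the maximum `-log10 p`
  member.
- **Analytic power** for the additive allelic test: with control allele
  frequency `p0`, case frequency `p1 = OR*q0/(1+OR*q0)`, `q0 = p0/(1-p0)`,
  the log-OR variance is `V = 1/(2 n_case p1 q1) + 1/(2 n_ctrl p0 q0)` and
  power is `Phi(|ln OR|/sqrt(V) - z_{1-a/2}) + Phi(-|ln OR|/sqrt(V) - z_{1-a/2})`.

## Worked example

```r
library(ctrlgwas)

cfg <- experiment_config(sim = sim_preset("confounded", seed = 11))
report <- run_strategy_comparison(cfg)
report
#> Control-selection strategy comparison
#>   all      n=5892 (510 cases): 3931 variants tested, max -log10P 22.32, 6 loci, lambda 1.336
#>   matched  n=2550 (510 cases): 3907 variants tested, max -log10P 19.97, 6 loci, lambda 1.120
#>   random   n=2550 (510 cases): 3928 variants tested, max -log10P 17.03, 5 loci, lambda 1.255
#>   loci in all three runs: 5 of 6 signals
```

Reading it: all three designs share the same 510 cases after QC. The full
design tests every eligible control and reaches the strongest signals; both
1:4 subsets lose peak `-log10 p` roughly in proportion to the lost
controls. The matched design's genomic inflation (1.12) sits well below the
random design's (1.26): matching on the genotype-derived PCs balances the
confounding subpopulation structure that regression adjustment only
partially removes (the twelve planted signals and their LD partners keep
every design's lambda above 1 — the comparison between designs is the
informative part).

Power and cost arithmetic:

```r
analytic_power(15250, 61000, maf = 0.03, odds_ratio = 1.5, alpha = 5e-8)
#> [1] 0.9999998   # ~100% at the 1:4 design point
resource_reduction(200000, 60000, 1)
#> [1] 70          # percent compute saved, linear algorithms
resource_reduction(200000, 60000, 2)
#> [1] 91          # percent, quadratic algorithms
```

Stability and ratio experiments:

```r
cohort <- simulate_cohort(cfg$sim)
seed_stability(cohort, cfg)          # random selection, seeds 1..10
ratio_sweep(cohort, cfg)             # matched designs, ratios 1:2..1:10
```

A thin command-line wrapper over the same functions is provided at
`inst/cli/ctrlgwas.R` (subcommands `simulate`, `compare`, `power`, `sweep`,
`stability`).

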