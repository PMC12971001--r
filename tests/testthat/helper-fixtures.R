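# Small programmatic fixtures and a cross-file cache for the expensive
# cohort-level computations shared by several acceptance checks.

# Minimal hand-rolled sample table with clean QC fields.
make_samples <- function(n, n_cases = floor(n / 5), seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    s <- data.frame(
      sample_id = sprintf("T%04d", seq_len(n)),
      reported_sex = "M", genetic_sex = "M",
      case_status = c(rep("case", n_cases), rep("control", n - n_cases)),
      age = runif(n, 40, 70),
      centre = sample(paste0("centre", 1:3), n, replace = TRUE),
      chip = sample(c("array1", "array2"), n, replace = TRUE),
      subpop = 1L,
      missing_rate = runif(n, 0, 0.02),
      heterozygosity = rnorm(n, 0.3, 0.01),
      aneuploidy_flag = FALSE,
      stringsAsFactors = FALSE)
    for (pc in paste0("PC", 1:10)) s[[pc]] <- rnorm(n)
    s
  })
}

# Summary-statistics table at explicit positions.
make_stats <- function(chrom, pos, log10p, id = sprintf("v%d", seq_along(pos)),
                       a0 = "A", a1 = "G") {
  data.frame(CHROM = chrom, GENPOS = pos, ID = id,
             ALLELE0 = a0, ALLELE1 = a1,
             A1FREQ = 0.3, N = 1000L, BETA = 0.1, SE = 0.02,
             CHISQ = qchisq(-log10p * log(10), df = 1, lower.tail = FALSE,
                            log.p = TRUE),
             LOG10P = log10p, stringsAsFactors = FALSE)
}

# Loci table at explicit lead positions.
make_loci <- function(chrom, lead_pos, lead_id = sprintf("L%d",
                                                         seq_along(lead_pos))) {
  data.frame(CHROM = chrom, START = lead_pos, END = lead_pos,
             N_VARIANTS = 1L, LEAD_ID = lead_id, LEAD_POS = lead_pos,
             LEAD_A0 = "A", LEAD_A1 = "G", LEAD_LOG10P = 10,
             stringsAsFactors = FALSE)
}

# Dosage fixture for LD-consistency checks: `n_high` run/ref lead pairs in
# perfect LD (duplicated columns) and the rest independent.
make_ld_fixture <- function(n_discordant, n_high, n = 400, seed = 99) {
  set.seed(seed)
  run_ids <- sprintf("run%02d", seq_len(n_discordant))
  ref_ids <- sprintf("ref%02d", seq_len(n_discordant))
  dos <- matrix(NA_real_, n, 2 * n_discordant,
                dimnames = list(sprintf("I%03d", seq_len(n)),
                                c(run_ids, ref_ids)))
  for (i in seq_len(n_discordant)) {
    x <- rbinom(n, 2, 0.3)
    dos[, run_ids[i]] <- x
    dos[, ref_ids[i]] <- if (i <= n_high) x else rbinom(n, 2, 0.3)
  }
  base <- (seq_len(n_discordant) - 1) * 10e6 + 1e6
  run_loci <- make_loci(1L, base + 1000, run_ids)
  ref_loci <- make_loci(1L, base, ref_ids)
  list(run = run_loci, ref = ref_loci, dosages = dos)
}

# Design whose controls are all non-case samples of the table.
new_design_for_test <- function(samples) {
  select_all(samples$sample_id[samples$case_status == "case"],
             samples$sample_id[samples$case_status == "control"])
}

# ---- shared cache for cohort-scale computations --------------------------

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Confounded-preset bundle: cohort, pools, all/matched designs + scans,
# lambda and concordance across the 10 random-selection seeds.
confounded_bundle <- function(sim_seed = 11L) {
  cache_get("confounded", function() {
    cohort <- simulate_cohort(sim_preset("confounded", seed = sim_seed))
    pools <- eligible_pools(cohort)
    scores <- estimate_propensity(pools$samples)
    analyse <- function(design) {
      fv <- filter_variants(cohort$variants, cohort$dosages,
                            c(design$cases, design$controls))
      stats <- run_gwas(cohort, design, fv$variants)
      list(design = design, stats = stats, loci = extract_loci(stats),
           lambda = genomic_lambda(stats))
    }
    all_run <- analyse(select_all(pools$cases, pools$pool))
    matched_run <- analyse(match_nearest(pools$cases, pools$pool, scores,
                                         selection_config("matched")))
    random_runs <- lapply(1:10, function(s) {
      analyse(select_random(pools$cases, pools$pool, 4L, s))
    })
    list(cohort = cohort, pools = pools, scores = scores,
         all = all_run, matched = matched_run, random = random_runs)
  })
}

# Matched-design ratio sweeps over replicate confounded cohorts, at the
# ratios entering the marginal-gain comparison.
sweep_replicates <- function(seeds = 21:23) {
  cache_get("sweeps", function() {
    lapply(seeds, function(s) {
      cohort <- simulate_cohort(sim_preset("confounded", seed = s))
      cfg <- experiment_config(ratio_list = c(2L, 6L, 10L))
      suppressMessages(suppressWarnings(ratio_sweep(cohort, cfg)))
    })
  })
}

# Null-preset calibration scan.
null_scan <- function(sim_seed = 5L) {
  cache_get("null", function() {
    cohort <- simulate_cohort(sim_preset("null", seed = sim_seed))
    pools <- eligible_pools(cohort)
    design <- select_all(pools$cases, pools$pool)
    fv <- filter_variants(cohort$variants, cohort$dosages,
                          c(design$cases, design$controls))
    run_gwas(cohort, design, fv$variants)
  })
}

# Planted-preset recovery over seeds: fraction of planted loci whose
# clumped lead lies within the window of the causal position.
planted_recovery <- function(seeds = 1:10, window = 5e5) {
  cache_get("planted", function() {
    hits <- 0L; total <- 0L
    per_seed <- integer(length(seeds))
    for (si in seq_along(seeds)) {
      cohort <- simulate_cohort(sim_preset("planted", seed = seeds[si]))
      pools <- eligible_pools(cohort)
      design <- select_all(pools$cases, pools$pool)
      fv <- filter_variants(cohort$variants, cohort$dosages,
                            c(design$cases, design$controls))
      stats <- run_gwas(cohort, design, fv$variants)
      lc <- extract_loci(stats)
      truth <- cohort$truth$causal
      for (i in seq_len(nrow(truth))) {
        pos <- cohort$variants$pos[
          which(cohort$variants$chrom == truth$chrom[i])[truth$rank[i]]]
        total <- total + 1L
        ok <- any(lc$CHROM == truth$chrom[i] &
                  abs(lc$LEAD_POS - pos) <= window)
        if (ok) {
          hits <- hits + 1L
          per_seed[si] <- per_seed[si] + 1L
        }
      }
    }
    list(hits = hits, total = total, rate = hits / total,
         per_seed = per_seed)
  })
}
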