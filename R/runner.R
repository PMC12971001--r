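#' Experiment configuration for the end-to-end pipeline
#'
#' @param sim A [sim_config()] (ignored when a prebuilt cohort is supplied
#'   to the runners).
#' @param strategies Subset of `c("all", "matched", "random")`.
#' @param ratio_k Case:control ratio for the matched and random designs
#'   (default 4).
#' @param random_seed Seed of the random selection (default 42).
#' @param ratio_list Ratios for the sweep experiment (default 2:10).
#' @param stability_seeds Seeds for the random-selection stability
#'   experiment (default 1:10).
#' @param chromosome_subset Chromosomes used by the stability experiment;
#'   `NULL` means the strongest-signal chromosome of the reference scan.
#' @param qc A [qc_config()].
#' @param loci A [loci_config()].
#' @param assoc An [assoc_config()].
#' @param out_dir Optional output directory for intermediate files.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_preset("confounded"),
                              strategies = c("all", "matched", "random"),
                              ratio_k = 4L, random_seed = 42L,
                              ratio_list = 2:10,
                              stability_seeds = 1:10,
                              chromosome_subset = NULL,
                              qc = qc_config(),
                              loci = loci_config(),
                              assoc = assoc_config(),
                              out_dir = NULL) {
  strategies <- match.arg(strategies, c("all", "matched", "random"),
                          several.ok = TRUE)
  assert_that(length(strategies) > 0, "strategies must be non-empty")
  assert_that(length(ratio_list) > 0, "ratio_list must be non-empty")
  assert_that(length(stability_seeds) > 0,
              "stability_seeds must be non-empty")
  structure(list(sim = sim, strategies = strategies,
                 ratio_k = as.integer(ratio_k),
                 random_seed = as.integer(random_seed),
                 ratio_list = as.integer(ratio_list),
                 stability_seeds = as.integer(stability_seeds),
                 chromosome_subset = chromosome_subset,
                 qc = qc, loci = loci, assoc = assoc,
                 out_dir = out_dir),
            class = "experiment_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_ctrlgwas(sprintf("stage '%s' failed: %s", stage,
                          conditionMessage(e)))
  })
}

# QC + design + per-design variant filtering + scan + loci for one strategy.
analyse_design <- function(cohort, design, config) {
  fv <- filter_variants(cohort$variants, cohort$dosages,
                        c(design$cases, design$controls), config$qc)
  stats <- run_gwas(cohort, design, fv$variants, config$assoc)
  list(design = design, stats = stats,
       variant_qc = fv$report,
       summary = summarize_stats(stats, config$loci),
       loci = extract_loci(stats, config$loci),
       lambda = genomic_lambda(stats))
}

#' Run the three-strategy comparison end to end
#'
#' Simulates (or accepts) a cohort, applies sample QC, builds each
#' configured design, recomputes variant-level QC within each design's
#' analysis cohort, runs the covariate-adjusted scan, extracts loci, and —
#' when the all-controls run is present together with others — compares the
#' runs (three-way Venn when all three exist, LD consistency of discordant
#' leads against the all-controls reference). Deterministic given the
#' config seeds.
#'
#' @param config An [experiment_config()].
#' @param cohort Optional prebuilt `cohort`; default simulates from
#'   `config$sim`.
#' @return An object of class `run_report`: per-strategy results
#'   (`designs`), the sample QC report, the comparison section (possibly
#'   empty), and provenance (seeds).
#' @export
run_strategy_comparison <- function(config, cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- run_stage("simulate", simulate_cohort(config$sim))
    log_stage("simulate", "cohort of %d samples, %d variants",
              nrow(cohort$samples),
              if (is.null(cohort$variants)) 0L else nrow(cohort$variants))
  }
  pools <- run_stage("qc", eligible_pools(cohort, config$qc))
  log_stage("qc", "%d cases, %d pool controls",
            length(pools$cases), length(pools$pool))
  scores <- NULL
  if ("matched" %in% config$strategies) {
    scores <- run_stage("propensity",
                        estimate_propensity(pools$samples))
  }
  designs <- list()
  for (s in config$strategies) {
    sel <- selection_config(s, ratio_k = config$ratio_k,
                            seed = config$random_seed)
    design <- run_stage(paste0("select-", s),
                        build_design(pools$samples, sel, scores = scores))
    log_stage(paste0("select-", s), "design of %d individuals (seed %s)",
              length(design$cases) + length(design$controls),
              design$seed)
    designs[[s]] <- run_stage(paste0("gwas-", s),
                              analyse_design(cohort, design, config))
    log_stage(paste0("gwas-", s),
              "%d variants tested, %d loci, lambda %.3f",
              nrow(designs[[s]]$stats), nrow(designs[[s]]$loci),
              designs[[s]]$lambda)
  }
  comparison <- list()
  if (all(c("all", "matched", "random") %in% config$strategies)) {
    comparison$venn <- run_stage("compare", venn_three(
      designs$all$loci, designs$matched$loci, designs$random$loci,
      config$loci$window_bp))
    ld_panel <- c(designs$all$design$cases, designs$all$design$controls)
    comparison$ld_matched <- run_stage("compare", ld_consistency(
      designs$matched$loci, designs$all$loci, cohort$dosages, ld_panel,
      config$loci$window_bp))
    comparison$ld_random <- run_stage("compare", ld_consistency(
      designs$random$loci, designs$all$loci, cohort$dosages, ld_panel,
      config$loci$window_bp))
  }
  report <- structure(list(designs = designs, sample_qc = pools$report,
                           comparison = comparison,
                           seeds = list(sim = cohort$truth$config$seed,
                                        random = config$random_seed)),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(report$designs)) {
    d <- report$designs[[s]]
    write_sumstats(d$stats, file.path(dir, paste0("sumstats_", s, ".tsv")))
    write_loci(d$loci, file.path(dir, paste0("loci_", s, ".tsv")))
    des <- d$design
    pairing_case <- rep(NA_character_, length(des$controls))
    if (!is.null(des$pairing)) {
      pairing_case <- rep(names(des$pairing),
                          vapply(des$pairing, length, 0L))
    }
    fwrite(data.frame(
      SAMPLE_ID = c(des$cases, des$controls),
      ROLE = c(rep("case", length(des$cases)),
               rep("control", length(des$controls))),
      MATCHED_CASE_ID = c(rep(NA_character_, length(des$cases)),
                          pairing_case),
      STRATEGY = s, SEED = des$seed),
      file.path(dir, paste0("design_", s, ".tsv")), sep = "\t", na = "NA")
  }
  summaries <- lapply(report$designs, function(d)
    c(d$summary, list(lambda = d$lambda, variant_qc = as.list(d$variant_qc))))
  jsonlite::write_json(
    list(schema = "ctrlgwas-report-1", summaries = summaries,
         sample_qc = report$sample_qc,
         comparison = report$comparison["venn"],
         seeds = report$seeds),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}

#' Stability of random control selection across seeds
#'
#' Repeats random 1:k selection, the association scan, and locus extraction
#' on a chromosome subset for each seed, and reports the per-seed locus
#' count, the modal count, and the seeds deviating from it.
#'
#' @param cohort A `cohort`.
#' @param config An [experiment_config()]; `stability_seeds` and
#'   `chromosome_subset` control the experiment.
#' @param ref_stats Optional reference `gwas_stats` used to pick the
#'   strongest-signal chromosome when `chromosome_subset` is `NULL`; when
#'   absent, an all-controls scan is run to find it.
#' @return List with `chrom`, per-seed `counts`, `modal`, `deviating_seeds`,
#'   and the per-seed `loci` list.
#' @export
seed_stability <- function(cohort, config = experiment_config(),
                           ref_stats = NULL) {
  pools <- eligible_pools(cohort, config$qc)
  chroms <- config$chromosome_subset
  if (is.null(chroms)) {
    if (is.null(ref_stats)) {
      all_design <- select_all(pools$cases, pools$pool)
      ref_stats <- analyse_design(cohort, all_design, config)$stats
    }
    chroms <- ref_stats$CHROM[which.max(ref_stats$LOG10P)]
    log_stage("stability", "strongest-signal chromosome: %s", chroms)
  }
  sub_variants <- cohort$variants[cohort$variants$chrom %in% chroms, ,
                                  drop = FALSE]
  counts <- integer(length(config$stability_seeds))
  loci_list <- vector("list", length(config$stability_seeds))
  for (i in seq_along(config$stability_seeds)) {
    sd_i <- config$stability_seeds[i]
    design <- select_random(pools$cases, pools$pool, config$ratio_k, sd_i)
    fv <- filter_variants(sub_variants, cohort$dosages,
                          c(design$cases, design$controls), config$qc)
    stats <- run_gwas(cohort, design, fv$variants, config$assoc)
    lc <- extract_loci(stats, config$loci)
    counts[i] <- nrow(lc)
    loci_list[[i]] <- lc
    log_stage("stability", "seed %d: %d locus/loci", sd_i, counts[i])
  }
  tab <- table(counts)
  modal <- as.integer(names(tab)[which.max(tab)])
  list(chrom = chroms,
       counts = setNames(counts, config$stability_seeds),
       modal = modal,
       deviating_seeds = config$stability_seeds[counts != modal],
       loci = loci_list)
}

#' Locus yield across case:control ratios in the matched design
#'
#' For each ratio k, builds the 1:k matched design (reusing one propensity
#' fit), runs the scan, and counts genome-wide significant loci: the table
#' behind a ratio-choice plot. Ratios the pool cannot support are dropped
#' with a warning.
#'
#' @param cohort A `cohort`.
#' @param config An [experiment_config()]; `ratio_list` sets the ratios.
#' @return Data.frame with columns `ratio`, `n_controls`, `n_loci`,
#'   `max_log10p`.
#' @export
ratio_sweep <- function(cohort, config = experiment_config()) {
  assert_that(length(config$ratio_list) > 0, "ratio_list must be non-empty")
  pools <- eligible_pools(cohort, config$qc)
  n_cases <- length(pools$cases)
  feasible <- config$ratio_list[config$ratio_list * n_cases <=
                                length(pools$pool)]
  if (length(feasible) < length(config$ratio_list)) {
    warning(sprintf(
      "pool of %d cannot support ratios above 1:%d; list truncated",
      length(pools$pool), max(c(feasible, 0L))), call. = FALSE)
  }
  assert_that(length(feasible) > 0,
              "control pool cannot support any requested ratio")
  scores <- estimate_propensity(pools$samples)
  rows <- lapply(feasible, function(k) {
    sel <- selection_config("matched", ratio_k = k)
    design <- match_nearest(pools$cases, pools$pool, scores, sel)
    res <- analyse_design(cohort, design, config)
    log_stage("sweep", "ratio 1:%d -> %d loci", k, nrow(res$loci))
    data.frame(ratio = k, n_controls = length(design$controls),
               n_loci = nrow(res$loci),
               max_log10p = res$summary$max_log10p)
  })
  do.call(rbind, rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Control-selection strategy comparison\n")
  for (s in names(x$designs)) {
    d <- x$designs[[s]]
    cat(sprintf(
      "  %-8s n=%d (%d cases): %d variants tested, max -log10P %.2f, %d loci, lambda %.3f\n",
      s, length(d$design$cases) + length(d$design$controls),
      length(d$design$cases), d$summary$n_total, d$summary$max_log10p,
      nrow(d$loci), d$lambda))
  }
  if (length(x$comparison)) {
    v <- x$comparison$venn
    cat(sprintf("  loci in all three runs: %d of %d signals\n",
                v$loci[["ABC"]], v$loci_union))
  }
  invisible(x)
}
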