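#' Quality-control configuration
#'
#' Sample- and variant-level thresholds: imputation INFO minimum 0.7, minor
#' allele frequency (MAF) minimum 1 percent, minor allele count (MAC)
#' minimum 5, a maximum per-sample missing-call rate, and a
#' standard-deviation multiplier for heterozygosity outliers.
#'
#' @param info_min Minimum imputation INFO score (default 0.7).
#' @param maf_min Minimum MAF (default 0.01), recomputed on the analysis
#'   cohort.
#' @param mac_min Minimum MAC (default 5), on rounded dosages.
#' @param miss_max Maximum per-sample missing rate (default 0.1).
#' @param het_sd Samples farther than `het_sd` standard deviations from the
#'   mean heterozygosity are removed (default 3).
#' @param exclude_sex_mismatch Drop samples whose reported and genetic sex
#'   disagree (default `TRUE`).
#' @param exclude_aneuploidy Drop samples flagged for sex-chromosome
#'   aneuploidy (default `TRUE`).
#' @param male_only Restrict to genetically male samples, as for a
#'   male-only phenotype (default `TRUE`).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(info_min = 0.7, maf_min = 0.01, mac_min = 5,
                      miss_max = 0.1, het_sd = 3,
                      exclude_sex_mismatch = TRUE,
                      exclude_aneuploidy = TRUE,
                      male_only = TRUE) {
  assert_that(is_prop(info_min) && is_prop(maf_min) && is_prop(miss_max),
              "info_min, maf_min, miss_max must be proportions")
  assert_that(mac_min >= 0 && het_sd > 0, "mac_min >= 0 and het_sd > 0")
  structure(list(info_min = info_min, maf_min = maf_min, mac_min = mac_min,
                 miss_max = miss_max, het_sd = het_sd,
                 exclude_sex_mismatch = isTRUE(exclude_sex_mismatch),
                 exclude_aneuploidy = isTRUE(exclude_aneuploidy),
                 male_only = isTRUE(male_only)),
            class = "qc_config")
}

#' Sample-level quality control
#'
#' Removes, in order: reported/genetic sex mismatches, sex-chromosome
#' aneuploidy, missing-rate outliers (`missing_rate > miss_max`),
#' heterozygosity outliers (`|het - mean| > het_sd * sd`, mean and sd taken
#' over samples surviving the earlier rules), and genetically female samples
#' for a male-only phenotype. Each sample is counted once under the first
#' rule it fails; the order of the remaining samples is preserved.
#'
#' @param samples Sample table of a `cohort`.
#' @param config A [qc_config()].
#' @return List with `samples` (the eligible rows) and `report` (named
#'   removal counts plus eligible case/control pool sizes).
#' @export
filter_samples <- function(samples, config = qc_config()) {
  n0 <- nrow(samples)
  removed <- c(sex_mismatch = 0L, aneuploidy = 0L, missing_outlier = 0L,
               het_outlier = 0L, non_male = 0L)
  keep <- rep(TRUE, n0)
  if (config$exclude_sex_mismatch) {
    bad <- keep & (samples$reported_sex != samples$genetic_sex)
    removed["sex_mismatch"] <- sum(bad)
    keep <- keep & !bad
  }
  if (config$exclude_aneuploidy) {
    bad <- keep & samples$aneuploidy_flag
    removed["aneuploidy"] <- sum(bad)
    keep <- keep & !bad
  }
  bad <- keep & !is.na(samples$missing_rate) &
    samples$missing_rate > config$miss_max
  removed["missing_outlier"] <- sum(bad)
  keep <- keep & !bad
  het <- samples$heterozygosity
  mu <- mean(het[keep], na.rm = TRUE)
  sg <- sd(het[keep], na.rm = TRUE)
  if (is.finite(sg) && sg > 0) {
    bad <- keep & !is.na(het) & abs(het - mu) > config$het_sd * sg
    removed["het_outlier"] <- sum(bad)
    keep <- keep & !bad
  }
  if (config$male_only) {
    bad <- keep & samples$genetic_sex != "M"
    removed["non_male"] <- sum(bad)
    keep <- keep & !bad
  }
  out <- samples[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop_ctrlgwas("no eligible samples after QC")
  report <- list(n_input = n0, removed = removed,
                 n_eligible = nrow(out),
                 n_cases = sum(out$case_status == "case"),
                 n_control_pool = sum(out$case_status == "control"))
  list(samples = out, report = report)
}

#' Recompute minor allele frequency on a sample subset
#'
#' MAF per variant is `min(f, 1 - f)` where `f` is the mean non-missing
#' dosage divided by 2 over the subset; missing entries are excluded from
#' the denominator. Variants with all dosages missing get `NA` and are
#' flagged in the `"undefined"` attribute.
#'
#' @param dosages Samples x variants dosage matrix (rownames are sample ids).
#' @param sample_ids Character vector of subset sample ids.
#' @return Named numeric vector of MAFs (attribute `a1freq` carries the
#'   allele-1 frequency `f`).
#' @export
recompute_maf <- function(dosages, sample_ids) {
  assert_that(length(sample_ids) > 0, "sample subset must be non-empty")
  idx <- match(sample_ids, rownames(dosages))
  assert_that(!anyNA(idx), "sample ids missing from dosage matrix")
  f <- colMeans(dosages[idx, , drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  undefined <- names(maf)[is.nan(f)]
  maf[is.nan(f)] <- NA_real_
  attr(maf, "a1freq") <- f
  attr(maf, "undefined") <- undefined
  maf
}

#' Variant-level quality control
#'
#' Drops variants with INFO below `info_min`, MAF (recomputed over the
#' analysis cohort) below `maf_min`, or MAC (minor-allele count on rounded
#' dosages over the analysis cohort) below `mac_min`. Each variant is
#' counted once under the first rule it fails, with precedence
#' INFO -> MAF -> MAC.
#'
#' @param variants Variant table.
#' @param dosages Dosage matrix.
#' @param sample_ids Analysis-cohort sample ids (cases plus selected
#'   controls).
#' @param config A [qc_config()].
#' @return List with `variants` (kept rows, `maf` column filled) and
#'   `report` (named per-rule removal counts).
#' @export
filter_variants <- function(variants, dosages, sample_ids,
                            config = qc_config()) {
  maf <- recompute_maf(dosages, sample_ids)
  maf <- maf[variants$variant_id]
  idx <- match(sample_ids, rownames(dosages))
  rd <- round(dosages[idx, variants$variant_id, drop = FALSE])
  a1 <- colSums(rd, na.rm = TRUE)
  n_obs <- colSums(!is.na(rd))
  mac <- pmin(a1, 2 * n_obs - a1)

  fail_info <- !is.na(variants$info) & variants$info < config$info_min
  fail_maf <- !fail_info & (is.na(maf) | maf < config$maf_min)
  fail_mac <- !fail_info & !fail_maf & mac < config$mac_min
  keep <- !(fail_info | fail_maf | fail_mac)
  out <- variants[keep, , drop = FALSE]
  out$maf <- unname(maf[keep])
  report <- c(info = sum(fail_info), maf = sum(fail_maf),
              mac = sum(fail_mac))
  list(variants = out, report = report)
}

#' Combined sample QC report and eligible pools
#'
#' Convenience wrapper: applies [filter_samples()] to a cohort and returns
#' the eligible case ids, the eligible control pool ids, and the QC report.
#'
#' @param cohort A `cohort`.
#' @param config A [qc_config()].
#' @return List with `cases`, `pool`, `samples` (eligible sample table) and
#'   `report`.
#' @export
eligible_pools <- function(cohort, config = qc_config()) {
  fs <- filter_samples(cohort$samples, config)
  s <- fs$samples
  list(cases = s$sample_id[s$case_status == "case"],
       pool = s$sample_id[s$case_status == "control"],
       samples = s,
       report = fs$report)
}
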