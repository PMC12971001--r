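#' Match loci across two association runs
#'
#' Two loci from different runs describe the same signal when their lead
#' SNPs sit within `window_bp` of each other on the same chromosome. Pairs
#' are formed per chromosome by a sorted two-pointer sweep over lead
#' positions (advance whichever side trails; pair when within the window),
#' which attains the maximum possible number of pairs for this interval
#' compatibility structure; each locus joins at most one pair. Unmatched
#' loci are listed as unique to their run.
#'
#' @param loci_a,loci_b `loci` tables from the same coordinate system.
#' @param window_bp Maximum lead-to-lead distance (default 500,000).
#' @return List with `pairs` (data.frame: index_a, index_b, lead_a, lead_b,
#'   distance), `unique_a`, `unique_b` (row indices).
#' @export
match_loci <- function(loci_a, loci_b, window_bp = 500000) {
  na <- nrow(loci_a); nb <- nrow(loci_b)
  used_a <- logical(na); used_b <- logical(nb)
  pairs <- NULL
  for (ch in intersect(loci_a$CHROM, loci_b$CHROM)) {
    ia <- which(loci_a$CHROM == ch)
    ib <- which(loci_b$CHROM == ch)
    ia <- ia[order(loci_a$LEAD_POS[ia])]
    ib <- ib[order(loci_b$LEAD_POS[ib])]
    i <- 1L; j <- 1L
    while (i <= length(ia) && j <= length(ib)) {
      pa <- loci_a$LEAD_POS[ia[i]]
      pb <- loci_b$LEAD_POS[ib[j]]
      if (abs(pa - pb) <= window_bp) {
        pairs <- rbind(pairs, data.frame(
          index_a = ia[i], index_b = ib[j],
          lead_a = loci_a$LEAD_ID[ia[i]], lead_b = loci_b$LEAD_ID[ib[j]],
          distance = abs(pa - pb), stringsAsFactors = FALSE))
        used_a[ia[i]] <- TRUE; used_b[ib[j]] <- TRUE
        i <- i + 1L; j <- j + 1L
      } else if (pa < pb) {
        i <- i + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(index_a = integer(0), index_b = integer(0),
                        lead_a = character(0), lead_b = character(0),
                        distance = numeric(0), stringsAsFactors = FALSE)
  }
  list(pairs = pairs, unique_a = which(!used_a), unique_b = which(!used_b))
}

#' Three-way locus and lead-SNP Venn counts
#'
#' Locus identity across the three runs is the transitive closure of the
#' pairwise lead-to-lead match (union-find over matched pairs); each
#' resulting signal cluster is counted once in the region named by the set
#' of runs it contains, so the seven region counts sum to the number of
#' distinct signals. A cluster containing two loci of the same run (an
#' inconsistent transitive chain) is kept, counted once, and flagged. The
#' lead-SNP Venn uses exact ID equality.
#'
#' @param loci_a,loci_b,loci_c `loci` tables (conventionally the all,
#'   matched, and random runs).
#' @param window_bp Lead-to-lead matching window.
#' @param labels Region label prefixes (default `c("A", "B", "C")`).
#' @return List with `loci` and `leads`, each a named 7-region count vector
#'   (`A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`), plus `n_union` for each and
#'   `flagged` cluster count.
#' @export
venn_three <- function(loci_a, loci_b, loci_c, window_bp = 500000,
                       labels = c("A", "B", "C")) {
  ns <- c(nrow(loci_a), nrow(loci_b), nrow(loci_c))
  offset <- c(0L, ns[1], ns[1] + ns[2])
  total <- sum(ns)
  parent <- seq_len(total)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[ry] <<- rx
  }
  ll <- list(loci_a, loci_b, loci_c)
  combos <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (cb in combos) {
    mm <- match_loci(ll[[cb[1]]], ll[[cb[2]]], window_bp)
    if (nrow(mm$pairs)) {
      for (r in seq_len(nrow(mm$pairs))) {
        union_(offset[cb[1]] + mm$pairs$index_a[r],
               offset[cb[2]] + mm$pairs$index_b[r])
      }
    }
  }
  run_of <- rep(1:3, ns)
  roots <- vapply(seq_len(total), find, 0L)
  region_names <- c(labels, paste0(labels[1], labels[2]),
                    paste0(labels[1], labels[3]),
                    paste0(labels[2], labels[3]),
                    paste0(labels[1], labels[2], labels[3]))
  counts <- setNames(rep(0L, 7L), region_names)
  flagged <- 0L
  if (total > 0) {
    for (cl in split(seq_len(total), roots)) {
      runs <- sort(unique(run_of[cl]))
      if (length(cl) > length(runs)) flagged <- flagged + 1L
      key <- paste(labels[runs], collapse = "")
      counts[key] <- counts[key] + 1L
    }
  }
  lead_sets <- list(loci_a$LEAD_ID, loci_b$LEAD_ID, loci_c$LEAD_ID)
  all_ids <- unique(unlist(lead_sets))
  lead_counts <- setNames(rep(0L, 7L), region_names)
  for (id in all_ids) {
    runs <- which(vapply(lead_sets, function(s) id %in% s, TRUE))
    key <- paste(labels[runs], collapse = "")
    lead_counts[key] <- lead_counts[key] + 1L
  }
  list(loci = counts, loci_union = sum(counts),
       leads = lead_counts, leads_union = length(all_ids),
       flagged = flagged)
}

#' Lead-SNP concordance between a run and a reference run
#'
#' Pairs loci across the two runs by lead-to-lead distance
#' ([match_loci()]) and reports how many paired loci carry the identical
#' lead SNP. The `rate` (shared leads over paired loci) measures
#' consistency of signal localization independently of how many loci each
#' run had the power to reach; the raw shared count is also returned.
#'
#' @param run_loci `loci` table under evaluation.
#' @param ref_loci Reference `loci` table.
#' @param window_bp Locus-matching window (default 500,000).
#' @return List with `n_pairs`, `n_shared_leads`, `rate` (`NA` when no loci
#'   pair up).
#' @export
lead_concordance <- function(run_loci, ref_loci, window_bp = 500000) {
  mm <- match_loci(run_loci, ref_loci, window_bp)
  n_pairs <- nrow(mm$pairs)
  n_shared <- if (n_pairs) sum(mm$pairs$lead_a == mm$pairs$lead_b) else 0L
  list(n_pairs = n_pairs, n_shared_leads = n_shared,
       rate = if (n_pairs > 0) n_shared / n_pairs else NA_real_)
}

#' Linkage-disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of the non-missing paired dosages over a
#' sample subset. Invariant under affine recoding of either dosage vector.
#'
#' @param dosages Samples x variants dosage matrix.
#' @param variant1,variant2 Variant IDs (columns of `dosages`).
#' @param sample_ids Sample subset (default all rows).
#' @return r-squared in `[0, 1]`; `NA` with a warning attribute when either
#'   vector has zero variance on the subset.
#' @export
ld_r2 <- function(dosages, variant1, variant2, sample_ids = NULL) {
  cols <- match(c(variant1, variant2), colnames(dosages))
  assert_that(!anyNA(cols), "both variants must be present in the dosages")
  if (is.null(sample_ids)) {
    idx <- seq_len(nrow(dosages))
  } else {
    idx <- match(sample_ids, rownames(dosages))
    assert_that(length(idx) > 0 && !anyNA(idx),
                "sample subset must be non-empty and present")
  }
  x <- dosages[idx, cols[1]]
  y <- dosages[idx, cols[2]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) {
    out <- NA_real_
    attr(out, "flag") <- "zero variance"
    return(out)
  }
  cor(x, y)^2
}

#' LD consistency of discordant lead SNPs
#'
#' For each lead SNP unique to a run (not shared by ID with the reference
#' run), finds the reference locus matched by lead-to-lead distance and
#' computes the dosage r-squared between the two leads over the reference
#' sample panel. Reports how many discordant leads exceed the threshold and
#' the percentage (two decimal places). Leads without a matched reference
#' locus are excluded from the denominator and counted separately.
#'
#' @param run_loci `loci` table of the run under evaluation.
#' @param ref_loci `loci` table of the reference run.
#' @param dosages Dosage matrix for the LD panel.
#' @param sample_ids LD panel sample ids (default all).
#' @param window_bp Locus-matching window.
#' @param r2_threshold High-LD threshold (default 0.8).
#' @return List with `n_discordant`, `n_high_ld`, `percentage` (rounded to
#'   2 decimals; `NA` when there are no discordant leads), `n_unmatched`,
#'   and the per-lead `table`.
#' @export
ld_consistency <- function(run_loci, ref_loci, dosages, sample_ids = NULL,
                           window_bp = 500000, r2_threshold = 0.8) {
  shared <- run_loci$LEAD_ID %in% ref_loci$LEAD_ID
  uniq <- which(!shared)
  mm <- match_loci(run_loci, ref_loci, window_bp)
  tab <- NULL
  n_unmatched <- 0L
  for (i in uniq) {
    j <- mm$pairs$index_b[mm$pairs$index_a == i]
    if (!length(j)) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    r2 <- ld_r2(dosages, run_loci$LEAD_ID[i], ref_loci$LEAD_ID[j],
                sample_ids)
    tab <- rbind(tab, data.frame(
      lead = run_loci$LEAD_ID[i], ref_lead = ref_loci$LEAD_ID[j],
      r2 = as.numeric(r2), stringsAsFactors = FALSE))
  }
  n_disc <- if (is.null(tab)) 0L else nrow(tab)
  n_high <- if (is.null(tab)) 0L else sum(!is.na(tab$r2) &
                                          tab$r2 > r2_threshold)
  pct <- if (n_disc > 0) round(100 * n_high / n_disc, 2) else NA_real_
  list(n_discordant = n_disc, n_high_ld = n_high, percentage = pct,
       n_unmatched = n_unmatched, table = tab)
}

#' Effect-size concordance against a benchmark SNP set
#'
#' Locates benchmark SNPs in the summary statistics (by ID, with a
#' chromosome+position fallback), harmonizes effect sizes to the benchmark
#' effect allele (the sign flips when the study's allele1 is the benchmark's
#' non-effect allele; allele pairs matching neither orientation are dropped
#' and counted), then regresses study beta on benchmark beta by ordinary
#' least squares. The adjusted R-squared uses the single-predictor
#' correction `1 - (1 - R2) (n - 1) / (n - 2)`.
#'
#' @param stats A `gwas_stats` table.
#' @param benchmark Data.frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `beta`.
#' @return List with `n_matched`, `n_dropped`, `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, and the merged `table`.
#' @export
effect_concordance <- function(stats, benchmark) {
  idx <- match(benchmark$id, stats$ID)
  fb <- is.na(idx)
  if (any(fb)) {
    key_s <- paste(stats$CHROM, stats$GENPOS)
    key_b <- paste(benchmark$chrom, benchmark$pos)
    idx[fb] <- match(key_b[fb], key_s)
  }
  found <- !is.na(idx)
  st <- stats[idx[found], , drop = FALSE]
  bm <- benchmark[found, , drop = FALSE]
  same <- st$ALLELE1 == bm$effect_allele
  flip <- st$ALLELE0 == bm$effect_allele
  usable <- same | flip
  n_dropped <- sum(!usable) + sum(!found)
  st <- st[usable, , drop = FALSE]
  bm <- bm[usable, , drop = FALSE]
  beta_study <- ifelse(same[usable], st$BETA, -st$BETA)
  n <- length(beta_study)
  if (n < 3) {
    stop_ctrlgwas(sprintf(
      "only %d benchmark SNPs matched; at least 3 required", n))
  }
  fit <- lm(beta_study ~ bm$beta)
  r2 <- summary(fit)$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(n_matched = n, n_dropped = n_dropped,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, adj_r_squared = adj,
       table = data.frame(id = bm$id, beta_benchmark = bm$beta,
                          beta_study = beta_study,
                          stringsAsFactors = FALSE))
}

#' Read / write a benchmark SNP table
#'
#' TSV columns: ID, CHROM, POS, EFFECT_ALLELE, BETA.
#'
#' @param path File path.
#' @param benchmark Benchmark data.frame (columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `beta`).
#' @return The benchmark data.frame (`read_benchmark`); `path` invisibly
#'   (`write_benchmark`).
#' @export
read_benchmark <- function(path) {
  b <- fread(path, sep = "\t", data.table = FALSE)
  out <- data.frame(id = b$ID, chrom = b$CHROM, pos = b$POS,
                    effect_allele = b$EFFECT_ALLELE, beta = b$BETA,
                    stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(out$id), "benchmark ids must be unique")
  out
}

#' @rdname read_benchmark
#' @export
write_benchmark <- function(benchmark, path) {
  fwrite(data.frame(ID = benchmark$id, CHROM = benchmark$chrom,
                    POS = benchmark$pos,
                    EFFECT_ALLELE = benchmark$effect_allele,
                    BETA = benchmark$beta),
         path, sep = "\t")
  invisible(path)
}

#' Synthetic LD-rescue scenario with known counts
#'
#' Builds a fully synthetic pair of locus tables plus a dosage panel in
#' which every lead of the evaluated run differs by ID from the reference
#' lead of the same signal, and exactly `n_high` of the `n_discordant` lead
#' pairs are in perfect LD (duplicated dosage columns) while the rest are
#' independent. Used to exercise the LD-consistency accounting end to end.
#'
#' @param n_discordant Number of discordant lead pairs.
#' @param n_high Number of pairs in high LD.
#' @param n Panel size (default 400).
#' @param seed Seed.
#' @return List with `run`, `ref` (loci tables) and `dosages`.
#' @export
ctrlgwas_ld_fixture <- function(n_discordant, n_high, n = 400L, seed = 1L) {
  assert_that(n_high <= n_discordant, "n_high must not exceed n_discordant")
  with_seed(seed, {
    run_ids <- sprintf("run%02d", seq_len(n_discordant))
    ref_ids <- sprintf("ref%02d", seq_len(n_discordant))
    dos <- matrix(NA_real_, n, 2L * n_discordant,
                  dimnames = list(sprintf("I%04d", seq_len(n)),
                                  c(run_ids, ref_ids)))
    for (i in seq_len(n_discordant)) {
      x <- rbinom(n, 2, 0.3)
      dos[, run_ids[i]] <- x
      dos[, ref_ids[i]] <- if (i <= n_high) x else rbinom(n, 2, 0.3)
    }
    base <- (seq_len(n_discordant) - 1) * 10e6 + 1e6
    mk <- function(pos, ids) {
      data.frame(CHROM = 1L, START = pos, END = pos, N_VARIANTS = 1L,
                 LEAD_ID = ids, LEAD_POS = pos, LEAD_A0 = "A",
                 LEAD_A1 = "G", LEAD_LOG10P = 10,
                 stringsAsFactors = FALSE)
    }
    list(run = mk(base + 1000, run_ids), ref = mk(base, ref_ids),
         dosages = dos)
  })
}

#' Simulate a synthetic benchmark/study effect-size pair
#'
#' Generates `n` SNPs whose benchmark and study betas share slope
#' `slope` with Gaussian noise scaled so the population R-squared equals
#' `r2`. Useful for validating [effect_concordance()] against a known
#' variance-explained level. The output is synthetic and carries no
#' information about any real benchmark.
#'
#' @param n Number of SNPs (default 269).
#' @param r2 Target population R-squared.
#' @param slope True slope (default 1).
#' @param beta_sd SD of the benchmark betas (default 0.1).
#' @param seed Seed.
#' @return List with `benchmark` (data.frame) and `stats` (minimal
#'   `gwas_stats`-like data.frame with matching IDs and alleles).
#' @export
simulate_benchmark_pair <- function(n = 269L, r2 = 0.82, slope = 1,
                                    beta_sd = 0.1, seed = 1L) {
  with_seed(seed, {
    id <- sprintf("bm%03d", seq_len(n))
    chrom <- sample(1:22, n, replace = TRUE)
    pos <- sample.int(5e7, n)
    a0 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    a1 <- vapply(a0, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1L), "")
    beta_b <- rnorm(n, 0, beta_sd)
    noise_sd <- abs(slope) * beta_sd * sqrt((1 - r2) / r2)
    beta_s <- slope * beta_b + rnorm(n, 0, noise_sd)
    benchmark <- data.frame(id = id, chrom = chrom, pos = pos,
                            effect_allele = a1, beta = beta_b,
                            stringsAsFactors = FALSE)
    stats <- data.frame(CHROM = chrom, GENPOS = pos, ID = id,
                        ALLELE0 = a0, ALLELE1 = a1,
                        BETA = beta_s, stringsAsFactors = FALSE)
    list(benchmark = benchmark, stats = stats)
  })
}
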