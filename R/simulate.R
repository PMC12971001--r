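#' Simulate a synthetic biobank cohort
#'
#' Generates a cohort with known truth: discrete subpopulations whose allele
#' frequencies follow a Balding-Nichols model around shared base frequencies,
#' LD blocks induced by a latent AR(1) Gaussian on haplotypes, a logistic
#' liability model for case status (with planted causal variants, covariate
#' effects, and subpopulation confounding), genotype-derived principal
#' components, and configurable QC artifacts. The config seed fully
#' determines the output.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort`: a list with elements `samples`
#'   (data.frame of participant records), `variants` (data.frame of variant
#'   records), `dosages` (samples x variants numeric matrix in `[0, 2]` with
#'   `NA` for missing, or `NULL` for covariates-only cohorts), and `truth`
#'   (generating config, subpopulation assignment, causal table).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_samples
    subpop <- sample.int(config$n_subpops, n, replace = TRUE)
    samples <- simulate_base_samples(n, subpop, config)
    cohort <- structure(list(samples = samples, variants = NULL,
                             dosages = NULL,
                             truth = list(config = config, subpop = subpop,
                                          causal = config$causal_effects)),
                        class = "cohort")
    if (config$variants_per_chromosome > 0) {
      geno <- simulate_genotypes(config, subpop, seed = NULL)
      cohort$truth$base_freq <- geno$variants$base_freq
      geno$variants$base_freq <- NULL
      cohort$variants <- geno$variants
      cohort$dosages <- geno$dosages
      rownames(cohort$dosages) <- samples$sample_id
    }
    cohort <- inject_artifacts(cohort, config, seed = NULL)
    cohort$samples <- add_principal_components(cohort, config)
    cohort <- assign_phenotypes(cohort, config, seed = NULL)
    cohort
  })
}

# Demographics and non-genetic covariates. Assessment-centre composition
# shifts with subpopulation so centre acts as a mild stratification proxy,
# as recruitment geography does in real biobanks.
simulate_base_samples <- function(n, subpop, config) {
  sample_id <- sprintf("S%06d", seq_len(n))
  genetic_sex <- ifelse(runif(n) < config$female_frac, "F", "M")
  age <- pmin(70, pmax(40, rnorm(n, 57, 8)))
  centres <- paste0("centre", 1:8)
  base_p <- c(0.16, 0.14, 0.14, 0.13, 0.12, 0.11, 0.10, 0.10)
  tilt <- c(0.04, 0.02, 0.01, 0, 0, -0.01, -0.02, -0.04)
  sp_score <- subpop_score(subpop)
  centre <- character(n)
  for (s in sort(unique(subpop))) {
    idx <- which(subpop == s)
    p <- base_p + tilt * mean(sp_score[idx])
    p <- pmax(p, 0.01); p <- p / sum(p)
    centre[idx] <- sample(centres, length(idx), replace = TRUE, prob = p)
  }
  chip <- sample(c("array1", "array2"), n, replace = TRUE,
                 prob = c(0.112, 0.888))
  data.frame(sample_id = sample_id,
             reported_sex = genetic_sex,
             genetic_sex = genetic_sex,
             case_status = rep("control", n),
             age = age, centre = centre, chip = chip,
             subpop = subpop,
             missing_rate = NA_real_, heterozygosity = NA_real_,
             aneuploidy_flag = FALSE,
             stringsAsFactors = FALSE)
}

# Centred, unit-scaled subpopulation score used both as the confounder on the
# liability scale and to simulate PCs when genotypes are absent.
subpop_score <- function(subpop) {
  if (length(unique(subpop)) <= 1L) return(rep(0, length(subpop)))
  as.numeric(scale(subpop))
}

#' Simulate genotype dosages with LD blocks and subpopulation differentiation
#'
#' Per-subpopulation allele frequencies are drawn from a Balding-Nichols Beta
#' distribution around a shared base frequency with parameter `fst` (`fst = 0`
#' gives no differentiation). Within each block of `block_size` consecutive
#' variants, the two haplotypes of every individual are obtained by
#' thresholding a latent AR(1) Gaussian (adjacent correlation
#' `within_block_rho`) at the frequency quantile, and the dosage is the sum of
#' the two haplotypes. Missing entries are inserted completely at random at
#' `missing_rate`.
#'
#' @param config A [sim_config()].
#' @param subpops Integer subpopulation assignment, length `n_samples`.
#' @param seed Seed for this step; defaults to `config$seed + 1`. Pass `NULL`
#'   to draw from the current RNG stream.
#' @return List with `variants` (data.frame: chrom, pos, variant_id, allele0,
#'   allele1, info, maf, is_causal) and `dosages` (n x m matrix).
#' @export
simulate_genotypes <- function(config, subpops, seed = config$seed + 1L) {
  validate_sim_config(config)
  assert_that(length(subpops) == config$n_samples,
              "subpops must have length n_samples")
  with_seed(seed, {
    n <- config$n_samples
    m_chr <- config$variants_per_chromosome
    nchr <- config$n_chromosomes
    rho <- config$within_block_rho
    sp_hap <- rep(subpops, 2L)

    var_list <- vector("list", nchr)
    dos_list <- vector("list", nchr)
    bases <- c("A", "C", "G", "T")
    for (chrom in seq_len(nchr)) {
      pos <- sort(sample.int(config$chromosome_length_bp, m_chr))
      a0 <- sample(bases, m_chr, replace = TRUE)
      a1 <- vapply(a0, function(b) sample(setdiff(bases, b), 1L), "")
      p_base <- runif(m_chr, config$base_maf_range[1], config$base_maf_range[2])
      is_causal <- rep(FALSE, m_chr)
      ce <- config$causal_effects
      if (!is.null(ce)) {
        here <- ce[ce$chrom == chrom, , drop = FALSE]
        if (nrow(here)) {
          is_causal[here$rank] <- TRUE
          if ("maf" %in% names(here)) {
            pin <- !is.na(here$maf)
            p_base[here$rank[pin]] <- here$maf[pin]
          }
        }
      }
      # Balding-Nichols subpopulation frequencies (m x S)
      S <- config$n_subpops
      if (config$fst > 0 && S > 1) {
        a <- p_base * (1 - config$fst) / config$fst
        b <- (1 - p_base) * (1 - config$fst) / config$fst
        freqs <- matrix(0, m_chr, S)
        for (s in seq_len(S)) freqs[, s] <- rbeta(m_chr, a, b)
        freqs <- pmin(pmax(freqs, 1e-4), 1 - 1e-4)
      } else {
        freqs <- matrix(p_base, m_chr, S)
      }
      qthr <- qnorm(freqs)                      # m x S latent thresholds
      dos <- matrix(0L, n, m_chr)
      no_ld <- config$block_size == 1L || rho == 0
      # independent variants: one latent draw for the whole chromosome
      starts <- if (no_ld) 1L else seq(1L, m_chr, by = config$block_size)
      block_len <- if (no_ld) m_chr else config$block_size
      for (st in starts) {
        en <- min(st + block_len - 1L, m_chr)
        B <- en - st + 1L
        Z <- matrix(rnorm(2L * n * B), 2L * n, B)
        if (!no_ld && B > 1L && rho > 0) {
          s2 <- sqrt(1 - rho^2)
          for (j in 2:B) Z[, j] <- rho * Z[, j - 1L] + s2 * Z[, j]
        }
        thr <- t(qthr[st:en, , drop = FALSE])[sp_hap, , drop = FALSE]
        alle <- Z < thr
        dos[, st:en] <- alle[seq_len(n), , drop = FALSE] +
          alle[n + seq_len(n), , drop = FALSE]
      }
      vid <- sprintf("snp%d_%d", chrom, pos)
      var_list[[chrom]] <- data.frame(
        chrom = chrom, pos = pos, variant_id = vid,
        allele0 = a0, allele1 = a1,
        info = NA_real_, maf = NA_real_, is_causal = is_causal,
        base_freq = p_base,
        stringsAsFactors = FALSE)
      colnames(dos) <- vid
      dos_list[[chrom]] <- dos
    }
    variants <- do.call(rbind, var_list)
    rownames(variants) <- NULL
    dosages <- do.call(cbind, dos_list)
    storage.mode(dosages) <- "double"
    if (config$missing_rate > 0) {
      miss <- runif(length(dosages)) < config$missing_rate
      dosages[miss] <- NA_real_
    }
    list(variants = variants, dosages = dosages)
  })
}

#' Assign case status from the liability model
#'
#' The log-odds of disease for eligible (genetically male) participants is
#' the prevalence intercept plus planted per-allele effects times dosage
#' (missing dosages mean-imputed), covariate effects (age per SD, chip
#' contrast), and `confounding_strength` times the subpopulation score.
#' Females and ineligible participants are never cases. With
#' `exact_counts` set, exactly that many cases are drawn among eligible
#' participants by risk-weighted sampling without replacement.
#'
#' @param cohort A `cohort` with genotypes present (unless the config is
#'   covariates-only).
#' @param config A [sim_config()].
#' @param seed Seed for this step; defaults to `config$seed + 2`.
#' @return The cohort with `case_status` filled; the realized case count is
#'   attached as attribute `n_cases` of the samples table.
#' @export
assign_phenotypes <- function(cohort, config, seed = config$seed + 2L) {
  with_seed(seed, {
    smp <- cohort$samples
    n <- nrow(smp)
    eta <- rep(config$prevalence_intercept, n)
    ce <- config$causal_effects
    if (!is.null(ce) && !is.null(cohort$dosages)) {
      for (i in seq_len(nrow(ce))) {
        idx <- which(cohort$variants$chrom == ce$chrom[i])[ce$rank[i]]
        d <- cohort$dosages[, idx]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        # centred so planted effects do not shift the prevalence the
        # intercept sets
        eta <- eta + ce$beta[i] * (d - mean(d))
      }
    }
    cev <- config$covariate_effect_sizes
    if (!is.null(cev["age"]) && !is.na(cev["age"]) && cev["age"] != 0) {
      eta <- eta + cev[["age"]] * as.numeric(scale(smp$age))
    }
    if ("chip" %in% names(cev) && cev[["chip"]] != 0) {
      x <- as.numeric(smp$chip == "array2")
      eta <- eta + cev[["chip"]] * (x - mean(x))
    }
    if (config$confounding_strength != 0) {
      eta <- eta + config$confounding_strength *
        subpop_score(cohort$truth$subpop)
    }
    eligible <- smp$genetic_sex == "M"
    status <- ifelse(eligible, "control", "ineligible")
    if (!is.null(config$exact_counts)) {
      n_cases <- as.integer(config$exact_counts[[1]])
      n_ctrl <- as.integer(config$exact_counts[[2]])
      assert_that(sum(eligible) == n_cases + n_ctrl,
                  "exact_counts must sum to the number of eligible samples")
      # weighted sampling without replacement via exponential keys
      # (Efraimidis-Spirakis), linear-time at biobank scale
      elig_idx <- which(eligible)
      w <- plogis(eta[elig_idx])
      keys <- rexp(length(elig_idx)) / w
      pick <- elig_idx[order(keys)[seq_len(n_cases)]]
      status[pick] <- "case"
    } else {
      p <- plogis(eta)
      is_case <- eligible & (runif(n) < p)
      status[is_case] <- "case"
    }
    smp$case_status <- status
    attr(smp, "n_cases") <- sum(status == "case")
    cohort$samples <- smp
    cohort
  })
}

#' Inject quality-control artifacts and imputation INFO scores
#'
#' Fills per-sample QC metrics (missing-call rate and heterozygosity,
#' observed from the dosage matrix when genotypes exist) and then marks the
#' configured proportions of samples with a reported/genetic sex mismatch,
#' sex-chromosome aneuploidy, an elevated missing rate, or extreme
#' heterozygosity. Per-variant INFO scores are drawn from the configured
#' Beta distribution.
#'
#' @param cohort A `cohort`.
#' @param config A [sim_config()].
#' @param seed Seed for this step; defaults to `config$seed + 3`.
#' @return The cohort with QC fields populated.
#' @export
inject_artifacts <- function(cohort, config, seed = config$seed + 3L) {
  with_seed(seed, {
    smp <- cohort$samples
    n <- nrow(smp)
    if (!is.null(cohort$dosages)) {
      smp$missing_rate <- rowMeans(is.na(cohort$dosages))
      rd <- round(cohort$dosages)
      smp$heterozygosity <- rowMeans(rd == 1, na.rm = TRUE)
      cohort$variants$info <- rbeta(nrow(cohort$variants),
                                    config$info_beta_params[1],
                                    config$info_beta_params[2])
    } else {
      smp$missing_rate <- rbeta(n, 2, 300)
      smp$heterozygosity <- rnorm(n, 0.32, 0.01)
    }
    rates <- config$artifact_rates
    rate_of <- function(nm) if (nm %in% names(rates)) rates[[nm]] else 0
    flag <- function(rate) runif(n) < rate
    mm <- flag(rate_of("sex_mismatch"))
    smp$reported_sex[mm] <- ifelse(smp$genetic_sex[mm] == "M", "F", "M")
    smp$aneuploidy_flag <- flag(rate_of("aneuploidy"))
    mo <- flag(rate_of("missingness_outlier"))
    smp$missing_rate[mo] <- runif(sum(mo), 0.12, 0.25)
    ho <- flag(rate_of("het_outlier"))
    smp$heterozygosity[ho] <- smp$heterozygosity[ho] +
      sample(c(-0.12, 0.12), sum(ho), replace = TRUE)
    cohort$samples <- smp
    cohort
  })
}

# Top principal components of the centred dosage matrix, thinned to at most
# `max_variants` evenly spaced variants; scores are scaled to unit variance.
# Falls back to subpopulation-score-plus-noise PCs for covariates-only
# cohorts or when pcs_from_genotypes is FALSE.
add_principal_components <- function(cohort, config, n_pcs = 10L) {
  smp <- cohort$samples
  n <- nrow(smp)
  if (config$pcs_from_genotypes && !is.null(cohort$dosages) &&
      ncol(cohort$dosages) >= n_pcs) {
    pcs <- compute_genotype_pcs(cohort$dosages,
                                max_variants = config$pca_max_variants,
                                n_pcs = n_pcs)
  } else {
    sc <- subpop_score(cohort$truth$subpop)
    pcs <- matrix(rnorm(n * n_pcs), n, n_pcs)
    pcs[, 1] <- 1.2 * sc + 0.6 * pcs[, 1]
    pcs <- scale(pcs)
  }
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  cbind(smp, as.data.frame(pcs))
}

#' Principal components of a dosage matrix
#'
#' Mean-imputes missing entries, centres columns, and extracts the leading
#' eigenvectors of the variant-variant covariance on an evenly thinned
#' variant subset. Scores are scaled to unit variance.
#'
#' @param dosages Samples x variants numeric matrix.
#' @param max_variants Maximum number of thinned variants used.
#' @param n_pcs Number of components returned.
#' @return Samples x `n_pcs` matrix of PC scores.
#' @export
compute_genotype_pcs <- function(dosages, max_variants = 400L, n_pcs = 10L) {
  m <- ncol(dosages)
  idx <- unique(round(seq(1L, m, length.out = min(m, max_variants))))
  X <- dosages[, idx, drop = FALSE]
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- cm[na_idx[, 2]]
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(X, 2, function(v) any(v != 0))
  X <- X[, keep, drop = FALSE]
  ev <- eigen(crossprod(X), symmetric = TRUE)
  k <- min(n_pcs, ncol(X))
  scores <- X %*% ev$vectors[, seq_len(k), drop = FALSE]
  scores <- apply(scores, 2, function(v) {
    s <- sd(v); if (s > 0) v / s else v
  })
  if (k < n_pcs) {
    pad <- matrix(rnorm(nrow(scores) * (n_pcs - k)), nrow(scores))
    scores <- cbind(scores, scale(pad))
  }
  scores
}

#' @export
print.cohort <- function(x, ...) {
  st <- table(factor(x$samples$case_status,
                     levels = c("case", "control", "ineligible")))
  cat("Synthetic cohort\n")
  cat(sprintf("  samples: %d (%d cases, %d controls, %d ineligible)\n",
              nrow(x$samples), st[["case"]], st[["control"]],
              st[["ineligible"]]))
  if (is.null(x$variants)) {
    cat("  genotypes: none (covariates-only cohort)\n")
  } else {
    cat(sprintf("  variants: %d on %d chromosome(s); %d planted causal\n",
                nrow(x$variants), length(unique(x$variants$chrom)),
                sum(x$variants$is_causal)))
    cat(sprintf("  dosage missingness: %.3f\n", mean(is.na(x$dosages))))
  }
  invisible(x)
}
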