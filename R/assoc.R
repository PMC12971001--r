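#' Association-scan configuration
#'
#' @param covariates Adjustment covariates (default the 13 of
#'   [default_covariates()]).
#' @param mac_min Minimum minor allele count for a variant to be tested
#'   (default 5).
#' @param irls_tol IRLS convergence tolerance (default 1e-8).
#' @param irls_max_iter Maximum IRLS iterations (default 25).
#' @return An object of class `assoc_config`.
#' @export
assoc_config <- function(covariates = default_covariates(), mac_min = 5,
                         irls_tol = 1e-8, irls_max_iter = 25L) {
  assert_that(irls_tol > 0, "irls_tol must be positive")
  structure(list(covariates = covariates, mac_min = mac_min,
                 irls_tol = irls_tol,
                 irls_max_iter = as.integer(irls_max_iter),
                 test = "wald"),
            class = "assoc_config")
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial-logit GLM by iteratively reweighted least squares and
#' returns the coefficient vector with its covariance from the inverse
#' observed information. Constant columns (other than the intercept) are
#' dropped before fitting; a remaining rank deficiency, non-convergence, or
#' quasi-separation (a coefficient running away to the boundary) is reported
#' through the `converged`/`separated` flags rather than an error, so a
#' per-variant scan can tally untestable variants.
#'
#' @param y 0/1 response vector.
#' @param X Design matrix including an intercept column.
#' @param tol IRLS tolerance (default 1e-8).
#' @param max_iter Maximum iterations (default 25).
#' @return List with `coefficients`, `vcov`, `converged`, `separated`,
#'   `rank`.
#' @export
fit_logistic <- function(y, X, tol = 1e-8, max_iter = 25L) {
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2,
                        function(v) any(v != v[1L])))
  Xk <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(
    glm.fit(Xk, y, family = binomial(),
            control = glm.control(epsilon = tol, maxit = max_iter)))
  p <- ncol(Xk)
  full_rank <- fit$rank == p
  separated <- fit$boundary ||
    any(abs(fit$coefficients[!is.na(fit$coefficients)]) > 30)
  converged <- fit$converged && full_rank && !separated
  vcov <- matrix(NA_real_, p, p, dimnames = list(colnames(Xk), colnames(Xk)))
  if (full_rank) {
    p1 <- seq_len(fit$rank)
    vc <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    vcov[p1, p1] <- vc
  }
  coefs <- structure(rep(NA_real_, ncol(X)), names = colnames(X))
  coefs[keep] <- fit$coefficients
  vcov_full <- matrix(NA_real_, ncol(X), ncol(X),
                      dimnames = list(colnames(X), colnames(X)))
  vcov_full[keep, keep] <- vcov
  list(coefficients = coefs, vcov = vcov_full, converged = converged,
       separated = separated, rank = fit$rank,
       dropped = colnames(X)[!keep])
}

# Warm-started IRLS for the per-variant scan: Newton steps with step-halving
# on a deviance increase, converged when the deviance change is below tol
# (relative) and the last step is small. Covariance from the inverse
# observed information at the optimum. Agreement with an independent
# logistic fit is a tested invariant.
irls_fit <- function(y, X, start, tol = 1e-8, max_iter = 25L) {
  b <- start
  eta <- drop(X %*% b)
  mu <- plogis(eta)
  dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                  (1 - y) * log(pmax(1 - mu, 1e-300)))
  converged <- FALSE
  separated <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    w <- mu * (1 - mu)
    if (all(w < 1e-12)) { separated <- TRUE; break }
    sw <- sqrt(w)
    Xw <- X * sw
    XtWX <- crossprod(Xw)
    score <- drop(crossprod(X, y - mu))
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    # step-halving if the deviance worsens
    for (h in 0:5) {
      b_new <- b + step / 2^h
      eta_new <- drop(X %*% b_new)
      mu_new <- plogis(eta_new)
      dev_new <- -2 * sum(y * log(pmax(mu_new, 1e-300)) +
                          (1 - y) * log(pmax(1 - mu_new, 1e-300)))
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
    }
    moved <- max(abs(b_new - b))
    b <- b_new; mu <- mu_new
    dd <- abs(dev - dev_new) / (abs(dev_new) + 0.1)
    dev <- dev_new
    if (max(abs(b)) > 30) { separated <- TRUE; break }
    if (dd < tol && moved < 1e-6) { converged <- TRUE; break }
  }
  se <- rep(NA_real_, length(b))
  if (converged) {
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(w))
    vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(vc)) converged <- FALSE else se <- sqrt(diag(vc))
  }
  list(beta = b, se = se, converged = converged, separated = separated)
}

#' Covariate-adjusted per-variant association scan
#'
#' For every variant, fits a logistic regression of case status on allele
#' dosage plus the configured covariates over the design's individuals and
#' reports the Wald test on the dosage coefficient. Samples with a missing
#' dosage are dropped for that variant only. Variants with minor allele
#' count below `mac_min`, zero dosage variance, or a non-convergent fit are
#' excluded, with reasons tallied in the `excluded` attribute. P-values are
#' computed in log space, so `LOG10P` does not underflow for extreme
#' signals.
#'
#' @param cohort A `cohort` with genotypes.
#' @param design A `study_design`.
#' @param variants Variant table to test (default: all cohort variants;
#'   typically the output of [filter_variants()] on the design cohort).
#' @param config An [assoc_config()].
#' @return An object of class `gwas_stats`: a data.frame with REGENIE-style
#'   columns CHROM, GENPOS, ID, ALLELE0, ALLELE1, A1FREQ, N, BETA, SE,
#'   CHISQ, LOG10P, sorted by (CHROM, GENPOS). Attributes: `strategy`,
#'   `n_cases`, `n_controls`, `excluded` (named counts), `seed`.
#' @export
run_gwas <- function(cohort, design, variants = NULL,
                     config = assoc_config()) {
  if (is.null(variants)) variants <- cohort$variants
  ids <- c(design$cases, design$controls)
  ridx <- match(ids, rownames(cohort$dosages))
  if (anyNA(ridx)) {
    stop_ctrlgwas("design sample ids missing from the dosage matrix")
  }
  smp <- cohort$samples[match(ids, cohort$samples$sample_id), , drop = FALSE]
  y <- as.numeric(smp$case_status == "case")
  C <- build_design_matrix(smp, config$covariates)
  n <- length(y)
  X <- cbind(C, DOSAGE = 0)
  pj <- ncol(X)

  vm <- match(variants$variant_id, colnames(cohort$dosages))
  assert_that(!anyNA(vm), "variant ids missing from the dosage matrix")
  nv <- nrow(variants)
  beta <- se <- a1f <- rep(NA_real_, nv)
  nn <- rep(NA_integer_, nv)
  reason <- rep(NA_character_, nv)
  # covariate-only (null) fit once; each variant fit warm-starts from it
  null_fit <- fit_logistic(y, C, config$irls_tol, 50L)
  start <- c(null_fit$coefficients, DOSAGE = 0)
  start[is.na(start)] <- 0
  for (i in seq_len(nv)) {
    d <- cohort$dosages[ridx, vm[i]]
    obs <- !is.na(d)
    dv <- d[obs]
    if (length(dv) == 0L || all(dv == dv[1L])) {
      reason[i] <- "zero variance"
      next
    }
    a1 <- sum(round(dv))
    mac <- min(a1, 2 * length(dv) - a1)
    if (mac < config$mac_min) {
      reason[i] <- "low MAC"
      next
    }
    if (all(obs)) {
      X[, pj] <- dv
      fit <- irls_fit(y, X, start, config$irls_tol, config$irls_max_iter)
    } else {
      Xi <- cbind(C[obs, , drop = FALSE], DOSAGE = dv)
      fit <- irls_fit(y[obs], Xi, start, config$irls_tol,
                      config$irls_max_iter)
    }
    if (!fit$converged) {
      reason[i] <- if (fit$separated) "separation" else "non-convergence"
      next
    }
    beta[i] <- fit$beta[pj]
    se[i] <- fit$se[pj]
    a1f[i] <- mean(dv) / 2
    nn[i] <- length(dv)
  }
  ok <- is.na(reason)
  out <- data.frame(CHROM = variants$chrom[ok], GENPOS = variants$pos[ok],
                    ID = variants$variant_id[ok],
                    ALLELE0 = variants$allele0[ok],
                    ALLELE1 = variants$allele1[ok],
                    A1FREQ = a1f[ok], N = nn[ok],
                    BETA = beta[ok], SE = se[ok],
                    stringsAsFactors = FALSE)
  out$CHISQ <- (out$BETA / out$SE)^2
  out$LOG10P <- chisq_to_log10p(out$CHISQ)
  if ("info" %in% names(variants)) out$INFO <- variants$info[ok]
  if ("maf" %in% names(variants)) out$MAF <- variants$maf[ok]
  out <- out[order(out$CHROM, out$GENPOS), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strategy") <- design$strategy
  attr(out, "n_cases") <- length(design$cases)
  attr(out, "n_controls") <- length(design$controls)
  attr(out, "seed") <- design$seed
  attr(out, "excluded") <- table(reason[!ok])
  class(out) <- c("gwas_stats", "data.frame")
  out
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chisq) / 0.4549364`, the observed median 1-df chi-square
#' statistic over its null median. Values above 1 indicate inflation from
#' stratification or confounding.
#'
#' @param stats A `gwas_stats` data.frame (or any table with a CHISQ
#'   column), or a numeric vector of chi-square statistics.
#' @return Numeric lambda.
#' @export
genomic_lambda <- function(stats) {
  chisq <- if (is.numeric(stats)) stats else stats$CHISQ
  assert_that(length(chisq) >= 100,
              "need at least 100 test statistics for a stable lambda")
  median(chisq) / CHISQ1_MEDIAN
}

#' Write / read REGENIE-flavoured summary statistics
#'
#' The TSV carries columns CHROM GENPOS ID ALLELE0 ALLELE1 A1FREQ N BETA SE
#' CHISQ LOG10P preceded by `##` metadata records (strategy, seed, case and
#' control counts). `read_sumstats` also accepts plain REGENIE-like TSVs
#' without the metadata header.
#'
#' @param stats A `gwas_stats`.
#' @param path Output file.
#' @return `path` invisibly (`write_sumstats`); a `gwas_stats`
#'   (`read_sumstats`).
#' @export
write_sumstats <- function(stats, path) {
  con <- file(path, "w")
  meta <- c(strategy = attr(stats, "strategy") %||% "NA",
            seed = attr(stats, "seed") %||% "NA",
            n_cases = attr(stats, "n_cases") %||% "NA",
            n_controls = attr(stats, "n_controls") %||% "NA")
  writeLines(sprintf("##%s=%s", names(meta), as.character(meta)), con)
  close(con)
  cols <- intersect(c("CHROM", "GENPOS", "ID", "ALLELE0", "ALLELE1",
                      "A1FREQ", "N", "BETA", "SE", "CHISQ", "LOG10P"),
                    names(stats))
  fwrite(as.data.frame(stats)[, cols], path, sep = "\t", na = "NA",
         append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  hdr <- readLines(path, n = 50)
  nmeta <- sum(startsWith(hdr, "##"))
  out <- fread(path, sep = "\t", skip = nmeta, na.strings = "NA",
               data.table = FALSE)
  if (nmeta > 0) {
    kv <- sub("^##", "", hdr[seq_len(nmeta)])
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    for (f in c("strategy")) {
      if (f %in% keys) attr(out, f) <- vals[keys == f]
    }
    for (f in c("seed", "n_cases", "n_controls")) {
      if (f %in% keys) attr(out, f) <- suppressWarnings(
        as.integer(vals[keys == f]))
    }
  }
  class(out) <- c("gwas_stats", "data.frame")
  out
}

#' @export
print.gwas_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics [%s]: %d variants tested\n",
              attr(x, "strategy") %||% "?", nrow(x)))
  cat(sprintf("  cases %s, controls %s; max -log10P %.2f\n",
              attr(x, "n_cases") %||% "?", attr(x, "n_controls") %||% "?",
              suppressWarnings(max(x$LOG10P))))
  ex <- attr(x, "excluded")
  if (!is.null(ex) && length(ex)) {
    cat("  excluded:", paste(sprintf("%s=%d", names(ex), ex),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
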