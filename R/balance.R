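#' Covariate balance diagnostics for a study design
#'
#' For every covariate (categoricals expanded to indicator contrasts) the
#' standardized mean difference SMD = (mean_case - mean_control) /
#' sqrt((var_case + var_control) / 2) is reported before selection (cases
#' versus the full eligible pool) and after selection (cases versus the
#' selected controls), together with empirical quantile-quantile (eQQ)
#' statistics: the maximum and mean absolute difference between case and
#' control quantiles evaluated at the smaller group's resolution. Constant
#' covariates get SMD 0 and a flag.
#'
#' @param design A `study_design`.
#' @param samples Sample table covering cases, selected controls, and pool.
#' @param pool Optional full eligible pool ids for the "before" column;
#'   defaults to every sample with control status in `samples`.
#' @param covariates Covariate names (default the 13).
#' @return An object of class `balance_report`: a data.frame with columns
#'   `covariate`, `smd_before`, `smd_after`, `eqq_max`, `eqq_mean`,
#'   `constant`, plus case/control counts as attributes.
#' @export
balance_diagnostics <- function(design, samples, pool = NULL,
                                covariates = default_covariates()) {
  if (is.null(pool)) {
    pool <- samples$sample_id[samples$case_status == "control"]
  }
  rows <- samples$sample_id
  ci <- match(design$cases, rows)
  si <- match(design$controls, rows)
  pi <- match(pool, rows)
  assert_that(!anyNA(ci) && !anyNA(si) && !anyNA(pi),
              "design/pool ids missing from sample table")
  X <- build_design_matrix(samples, covariates, intercept = FALSE)
  res <- lapply(colnames(X), function(cn) {
    x <- X[, cn]
    xc <- x[ci]; xs <- x[si]; xp <- x[pi]
    const <- var(xc) == 0 && var(xs) == 0
    data.frame(covariate = cn,
               smd_before = smd(xc, xp),
               smd_after = smd(xc, xs),
               eqq_max = eqq_stat(xc, xs, max),
               eqq_mean = eqq_stat(xc, xs, mean),
               constant = const,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_cases") <- length(ci)
  attr(out, "n_controls") <- length(si)
  attr(out, "n_pool") <- length(pi)
  class(out) <- c("balance_report", "data.frame")
  out
}

smd <- function(a, b) {
  denom <- sqrt((var(a) + var(b)) / 2)
  if (!is.finite(denom) || denom == 0) return(0)
  (mean(a) - mean(b)) / denom
}

eqq_stat <- function(a, b, fun) {
  n <- min(length(a), length(b))
  if (n == 0L) return(NA_real_)
  p <- (seq_len(n) - 0.5) / n
  fun(abs(quantile(a, p, names = FALSE, type = 7) -
          quantile(b, p, names = FALSE, type = 7)))
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Covariate balance: %d cases vs %d selected controls (pool %d)\n",
              attr(x, "n_cases"), attr(x, "n_controls"), attr(x, "n_pool")))
  cat(sprintf("  mean |SMD| before: %.4f   after: %.4f\n",
              mean(abs(x$smd_before)), mean(abs(x$smd_after))))
  print.data.frame(head(as.data.frame(x), 15), row.names = FALSE,
                   digits = 3)
  if (nrow(x) > 15) cat(sprintf("  ... %d more covariates\n", nrow(x) - 15))
  invisible(x)
}
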