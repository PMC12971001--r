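#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils head tail modifyList
#' @importFrom data.table fread fwrite data.table as.data.table setDF
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_ctrlgwas <- function(..., call. = FALSE) stop(..., call. = call.)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_ctrlgwas(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

is_prop <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

#' Default GWAS covariate set
#'
#' The thirteen covariates used throughout: recruitment age, assessment
#' centre, genotyping chip, and the first ten genetic principal components.
#'
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function() {
  c("age", "centre", "chip", paste0("PC", 1:10))
}

# Build a covariate design matrix with intercept. Factor/character columns are
# expanded to indicator contrasts with the most frequent level as reference;
# numeric columns enter as-is. Constant columns are dropped (recorded in the
# "dropped" attribute).
build_design_matrix <- function(samples, covariates, intercept = TRUE) {
  missing_cov <- setdiff(covariates, names(samples))
  if (length(missing_cov)) {
    stop_ctrlgwas("covariates not found in sample table: ",
                  paste(missing_cov, collapse = ", "))
  }
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, nrow(samples))
  dropped <- character(0)
  for (cv in covariates) {
    x <- samples[[cv]]
    if (is.numeric(x)) {
      if (length(unique(x)) <= 1L) {
        dropped <- c(dropped, cv)
        next
      }
      cols[[cv]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      tab <- sort(table(x), decreasing = TRUE)
      lev <- names(tab)
      if (length(lev) <= 1L) {
        dropped <- c(dropped, cv)
        next
      }
      for (lv in lev[-1L]) {
        cols[[paste0(cv, lv)]] <- as.numeric(x == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- samples$sample_id
  attr(X, "dropped") <- dropped
  X
}

# Two-sided -log10 p from a 1-df chi-square statistic, computed in log space
# so extreme statistics (log10p > 300) do not underflow.
chisq_to_log10p <- function(chisq) {
  -pchisq(chisq, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# Median of the 1-df chi-square distribution, the genomic-control null median.
CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

# Format a proportion the way association summaries print it: two significant
# figures in scientific notation (e.g. 3.4e-04).
format_proportion <- function(p) {
  ifelse(p == 0, "0", formatC(p, digits = 1, format = "e"))
}
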