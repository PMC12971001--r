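#' Locus-extraction configuration
#'
#' @param sig_log10p Genome-wide significance on the -log10 scale
#'   (default `-log10(5e-8)` = 7.30103; variants must exceed it strictly,
#'   i.e. p < 5e-8).
#' @param suggestive_log10p Suggestive threshold (default 5, p < 1e-5).
#' @param window_bp Clumping window in base pairs (default 500,000).
#' @param method `"chain"` (single-linkage: variants within the window of
#'   each other chain into one locus, so loci can exceed twice the window)
#'   or `"lead-window"` (greedy fixed windows around successive leads).
#' @return An object of class `loci_config`.
#' @export
loci_config <- function(sig_log10p = -log10(5e-8), suggestive_log10p = 5,
                        window_bp = 500000,
                        method = c("chain", "lead-window")) {
  assert_that(sig_log10p >= suggestive_log10p,
              "significant threshold must not be below the suggestive one")
  assert_that(window_bp > 0, "window_bp must be positive")
  structure(list(sig_log10p = sig_log10p,
                 suggestive_log10p = suggestive_log10p,
                 window_bp = window_bp, method = match.arg(method)),
            class = "loci_config")
}

#' Significance and quality filtering of summary statistics
#'
#' Retains variants with `LOG10P` strictly greater than the threshold
#' (equivalent to p strictly below the printed p-value threshold) that also
#' pass the variant-quality thresholds when INFO/MAF columns are present.
#' Counts for both the significant and suggestive tiers are attached.
#'
#' @param stats A `gwas_stats` table.
#' @param threshold -log10 p threshold (default genome-wide).
#' @param config A [loci_config()] supplying the tier thresholds.
#' @param quality Optional [qc_config()]; applied to INFO/MAF columns when
#'   they exist in `stats`.
#' @return The retained subset, with attributes `n_significant` and
#'   `n_suggestive`.
#' @export
filter_significant <- function(stats, threshold = NULL,
                               config = loci_config(), quality = NULL) {
  if (is.null(threshold)) threshold <- config$sig_log10p
  ok <- rep(TRUE, nrow(stats))
  if (!is.null(quality)) {
    if ("INFO" %in% names(stats)) {
      ok <- ok & (is.na(stats$INFO) | stats$INFO >= quality$info_min)
    }
    if ("MAF" %in% names(stats)) {
      ok <- ok & (is.na(stats$MAF) | stats$MAF >= quality$maf_min)
    }
  }
  out <- stats[ok & stats$LOG10P > threshold, , drop = FALSE]
  attr(out, "n_significant") <- sum(ok & stats$LOG10P > config$sig_log10p)
  attr(out, "n_suggestive") <- sum(ok & stats$LOG10P > config$suggestive_log10p)
  out
}

#' Distance-based locus clumping
#'
#' Groups significant variants into loci per chromosome. Under the default
#' single-linkage `"chain"` rule, positions are sorted and a new locus
#' starts whenever the gap to the previous variant exceeds `window_bp`
#' (a gap exactly equal to the window still chains); this equals the
#' transitive closure of the "within the window of each other" relation.
#' Every variant belongs to exactly one locus. The lead SNP of a locus is
#' its maximum `LOG10P` member, ties broken by smaller position then
#' lexicographically smaller ID.
#'
#' @param stats Significant-variant table with CHROM, GENPOS, ID, LOG10P
#'   (and optionally ALLELE0/ALLELE1).
#' @param window_bp Clumping window (default 500,000).
#' @param method See [loci_config()].
#' @return An object of class `loci`: a data.frame with one row per locus
#'   (CHROM, START, END, N_VARIANTS, LEAD_ID, LEAD_POS, LEAD_A0, LEAD_A1,
#'   LEAD_LOG10P) and a `members` attribute listing member variant IDs.
#' @export
cluster_loci <- function(stats, window_bp = 500000,
                         method = c("chain", "lead-window")) {
  method <- match.arg(method)
  if (nrow(stats) == 0L) {
    out <- data.frame(CHROM = integer(0), START = numeric(0),
                      END = numeric(0), N_VARIANTS = integer(0),
                      LEAD_ID = character(0), LEAD_POS = numeric(0),
                      LEAD_A0 = character(0), LEAD_A1 = character(0),
                      LEAD_LOG10P = numeric(0), stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    class(out) <- c("loci", "data.frame")
    return(out)
  }
  st <- stats[order(stats$CHROM, stats$GENPOS), , drop = FALSE]
  groups <- vector("list", 0L)
  for (ch in unique(st$CHROM)) {
    sub <- st[st$CHROM == ch, , drop = FALSE]
    if (method == "chain") {
      gap <- c(Inf, diff(sub$GENPOS))
      gid <- cumsum(gap > window_bp)
    } else {
      gid <- lead_window_groups(sub, window_bp)
    }
    groups <- c(groups, split(sub, gid))
  }
  rows <- lapply(groups, function(g) {
    lead <- locus_lead(g)
    data.frame(CHROM = g$CHROM[1L], START = min(g$GENPOS),
               END = max(g$GENPOS), N_VARIANTS = nrow(g),
               LEAD_ID = lead$ID, LEAD_POS = lead$GENPOS,
               LEAD_A0 = lead$ALLELE0 %||% NA_character_,
               LEAD_A1 = lead$ALLELE1 %||% NA_character_,
               LEAD_LOG10P = lead$LOG10P, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$CHROM, out$START), , drop = FALSE]
  members <- lapply(groups, function(g) g$ID)
  members <- members[order(vapply(groups, function(g) g$CHROM[1L], 0),
                           vapply(groups, function(g) min(g$GENPOS), 0))]
  rownames(out) <- NULL
  attr(out, "members") <- members
  class(out) <- c("loci", "data.frame")
  out
}

# Greedy fixed-window alternative: repeatedly take the most significant
# unassigned variant as a lead and absorb everything within +-window of it.
lead_window_groups <- function(sub, window_bp) {
  gid <- rep(NA_integer_, nrow(sub))
  g <- 0L
  while (anyNA(gid)) {
    g <- g + 1L
    free <- which(is.na(gid))
    lead <- free[order(-sub$LOG10P[free], sub$GENPOS[free],
                       sub$ID[free])][1L]
    inwin <- free[abs(sub$GENPOS[free] - sub$GENPOS[lead]) <= window_bp]
    gid[inwin] <- g
  }
  gid
}

# Lead SNP of one locus: argmax LOG10P, ties by smaller position then ID.
locus_lead <- function(g) {
  g[order(-g$LOG10P, g$GENPOS, g$ID), , drop = FALSE][1L, , drop = FALSE]
}

#' Lead SNP of a locus member table
#'
#' @param members Data.frame of member variants with GENPOS, ID, LOG10P.
#' @return The single lead-variant row (maximum `LOG10P`; ties broken by
#'   smaller position, then lexicographically smaller ID).
#' @export
lead_snp <- function(members) {
  assert_that(nrow(members) > 0, "locus has no members")
  locus_lead(members)
}

#' Table-style summary of an association scan
#'
#' Reports the total number of tested variants, the maximum -log10 p, and
#' the counts and proportions of genome-wide significant and suggestive
#' variants. Proportions are additionally formatted to two significant
#' figures in scientific notation, matching how association summaries are
#' printed.
#'
#' @param stats A `gwas_stats` table.
#' @param config A [loci_config()].
#' @return A list with `n_total`, `max_log10p`, `n_significant`,
#'   `n_suggestive`, `prop_significant`, `prop_suggestive`,
#'   `prop_significant_fmt`, `prop_suggestive_fmt`.
#' @export
summarize_stats <- function(stats, config = loci_config()) {
  n <- nrow(stats)
  ns <- sum(stats$LOG10P > config$sig_log10p)
  nu <- sum(stats$LOG10P > config$suggestive_log10p)
  ps <- if (n > 0) ns / n else 0
  pu <- if (n > 0) nu / n else 0
  list(n_total = n,
       max_log10p = if (n > 0) max(stats$LOG10P) else NA_real_,
       n_significant = ns, n_suggestive = nu,
       prop_significant = ps, prop_suggestive = pu,
       prop_significant_fmt = format_proportion(ps),
       prop_suggestive_fmt = format_proportion(pu))
}

#' Extract loci from summary statistics
#'
#' Convenience pipeline: [filter_significant()] then [cluster_loci()].
#'
#' @param stats A `gwas_stats` table.
#' @param config A [loci_config()].
#' @param quality Optional [qc_config()] for variant-quality filtering.
#' @return A `loci` table.
#' @export
extract_loci <- function(stats, config = loci_config(), quality = NULL) {
  sig <- filter_significant(stats, config$sig_log10p, config, quality)
  cluster_loci(sig, config$window_bp, config$method)
}

#' Write a loci table as TSV
#'
#' @param loci A `loci` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  fwrite(as.data.frame(loci), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @export
print.loci <- function(x, ...) {
  cat(sprintf("%d locus/loci on %d chromosome(s)\n", nrow(x),
              length(unique(x$CHROM))))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
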