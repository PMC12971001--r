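#' Write a cohort to plain-text files
#'
#' Serializes a cohort to a directory of TSV files: `samples.tsv`
#' (SAMPLE_ID, REPORTED_SEX, GENETIC_SEX, STATUS, AGE, CENTRE, CHIP,
#' PC1..PC10, MISS_RATE, HET, ANEUPLOIDY), `variants.tsv` (CHROM, POS, ID,
#' ALLELE0, ALLELE1, INFO), and `dosages.tsv` (one row per variant: ID then
#' per-sample dosages, missing encoded as `NA`). With `include_truth = TRUE`
#' the generating truth (subpopulation assignment, causal table, config) is
#' written alongside so the round trip is lossless; with `FALSE` truth fields
#' stay private. Recomputed MAF is a derived quantity and is not serialized.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @param include_truth Write truth files (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, include_truth = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  smp <- cohort$samples
  pcs <- paste0("PC", 1:10)
  out <- data.frame(SAMPLE_ID = smp$sample_id,
                    REPORTED_SEX = smp$reported_sex,
                    GENETIC_SEX = smp$genetic_sex,
                    STATUS = smp$case_status,
                    AGE = smp$age, CENTRE = smp$centre, CHIP = smp$chip,
                    stringsAsFactors = FALSE)
  for (pc in pcs) out[[pc]] <- smp[[pc]]
  out$MISS_RATE <- smp$missing_rate
  out$HET <- smp$heterozygosity
  out$ANEUPLOIDY <- as.integer(smp$aneuploidy_flag)
  fwrite(out, file.path(dir, "samples.tsv"), sep = "\t", na = "NA")
  if (!is.null(cohort$variants)) {
    v <- cohort$variants
    fwrite(data.frame(CHROM = v$chrom, POS = v$pos, ID = v$variant_id,
                      ALLELE0 = v$allele0, ALLELE1 = v$allele1,
                      INFO = v$info),
           file.path(dir, "variants.tsv"), sep = "\t", na = "NA")
    dos <- as.data.table(t(cohort$dosages))
    setnames_safe(dos, smp$sample_id)
    dos <- cbind(data.table(ID = v$variant_id), dos)
    fwrite(dos, file.path(dir, "dosages.tsv"), sep = "\t", na = "NA")
  }
  if (include_truth) {
    fwrite(data.frame(SAMPLE_ID = smp$sample_id,
                      SUBPOP = cohort$truth$subpop),
           file.path(dir, "truth_subpop.tsv"), sep = "\t")
    if (!is.null(cohort$truth$causal)) {
      fwrite(cohort$truth$causal, file.path(dir, "truth_causal.tsv"),
             sep = "\t", na = "NA")
    }
    cfg <- cohort$truth$config
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

setnames_safe <- function(dt, nms) {
  data.table::setnames(dt, seq_along(nms), nms)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort TSVs.
#' @return A `cohort`. Malformed inputs (dimension mismatches between the
#'   sample table, variant table and dosage matrix) raise errors naming the
#'   offending file and the expected versus observed counts.
#' @export
read_cohort <- function(dir) {
  spath <- file.path(dir, "samples.tsv")
  assert_that(file.exists(spath), paste0("missing ", spath))
  s <- fread(spath, sep = "\t", na.strings = "NA", data.table = FALSE)
  need <- c("SAMPLE_ID", "REPORTED_SEX", "GENETIC_SEX", "STATUS", "AGE",
            "CENTRE", "CHIP", paste0("PC", 1:10), "MISS_RATE", "HET",
            "ANEUPLOIDY")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    stop_ctrlgwas("samples.tsv (line 1): missing columns ",
                  paste(miss, collapse = ", "))
  }
  samples <- data.frame(sample_id = s$SAMPLE_ID,
                        reported_sex = s$REPORTED_SEX,
                        genetic_sex = s$GENETIC_SEX,
                        case_status = s$STATUS,
                        age = s$AGE, centre = s$CENTRE, chip = s$CHIP,
                        subpop = NA_integer_,
                        missing_rate = s$MISS_RATE,
                        heterozygosity = s$HET,
                        aneuploidy_flag = as.logical(s$ANEUPLOIDY),
                        stringsAsFactors = FALSE)
  for (pc in paste0("PC", 1:10)) samples[[pc]] <- s[[pc]]

  variants <- NULL
  dosages <- NULL
  vpath <- file.path(dir, "variants.tsv")
  if (file.exists(vpath)) {
    v <- fread(vpath, sep = "\t", na.strings = "NA", data.table = FALSE)
    variants <- data.frame(chrom = v$CHROM, pos = v$POS, variant_id = v$ID,
                           allele0 = v$ALLELE0, allele1 = v$ALLELE1,
                           info = v$INFO, maf = NA_real_, is_causal = FALSE,
                           stringsAsFactors = FALSE)
    dpath <- file.path(dir, "dosages.tsv")
    assert_that(file.exists(dpath), paste0("missing ", dpath))
    d <- fread(dpath, sep = "\t", na.strings = "NA")
    if (nrow(d) != nrow(variants)) {
      stop_ctrlgwas(sprintf(
        "dosages.tsv: dimension mismatch at line %d: expected %d variant rows, found %d",
        nrow(d) + 1L, nrow(variants), nrow(d)))
    }
    if (ncol(d) != nrow(samples) + 1L) {
      stop_ctrlgwas(sprintf(
        "dosages.tsv (line 1): expected %d sample columns, found %d",
        nrow(samples), ncol(d) - 1L))
    }
    if (!identical(as.character(d[[1]]), variants$variant_id)) {
      stop_ctrlgwas("dosages.tsv: variant IDs do not match variants.tsv")
    }
    dosages <- t(as.matrix(d[, -1, drop = FALSE]))
    dimnames(dosages) <- list(samples$sample_id, variants$variant_id)
  }

  truth <- list(config = NULL, subpop = NULL, causal = NULL)
  tpath <- file.path(dir, "truth_subpop.tsv")
  if (file.exists(tpath)) {
    tt <- fread(tpath, sep = "\t", data.table = FALSE)
    truth$subpop <- tt$SUBPOP[match(samples$sample_id, tt$SAMPLE_ID)]
    samples$subpop <- truth$subpop
  }
  cpath <- file.path(dir, "truth_causal.tsv")
  if (file.exists(cpath)) {
    truth$causal <- fread(cpath, sep = "\t", na.strings = "NA",
                          data.table = FALSE)
    if (!is.null(variants)) {
      for (i in seq_len(nrow(truth$causal))) {
        idx <- which(variants$chrom == truth$causal$chrom[i])[truth$causal$rank[i]]
        variants$is_causal[idx] <- TRUE
      }
    }
  }
  jpath <- file.path(dir, "config.json")
  if (file.exists(jpath)) {
    raw <- jsonlite::read_json(jpath, simplifyVector = TRUE)
    raw$causal_effects <- if (is.null(raw$causal_effects)) NULL else
      as.data.frame(raw$causal_effects)
    raw$covariate_effect_sizes <- unlist(raw$covariate_effect_sizes)
    raw$artifact_rates <- unlist(raw$artifact_rates)
    raw$exact_counts <- if (is.null(raw$exact_counts)) NULL else
      unlist(raw$exact_counts)
    truth$config <- do.call(sim_config, raw)
  }
  structure(list(samples = samples, variants = variants, dosages = dosages,
                 truth = truth),
            class = "cohort")
}
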