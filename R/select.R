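#' Control-selection configuration
#'
#' @param strategy One of `"all"`, `"random"`, `"matched"`.
#' @param ratio_k Controls per case (default 4).
#' @param seed Seed for random selection (default 42).
#' @param ps_covariates Covariates of the propensity model (default the 13
#'   of [default_covariates()]).
#' @param caliper Optional maximum propensity-score distance; pairs beyond
#'   it are not formed (default none).
#' @param case_order Order in which cases are matched: `"descending"`
#'   propensity score (hardest-to-match first, the default) or
#'   `"data-order"`.
#' @param passes `"simultaneous"` (each case takes its `ratio_k` nearest
#'   available controls at once, the default) or `"sequential"` (`ratio_k`
#'   rounds of 1:1 matching).
#' @param allow_partial Permit incomplete matching when the pool runs short
#'   (default `FALSE`).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(strategy = c("all", "random", "matched"),
                             ratio_k = 4L, seed = 42L,
                             ps_covariates = default_covariates(),
                             caliper = NULL,
                             case_order = c("descending", "data-order"),
                             passes = c("simultaneous", "sequential"),
                             allow_partial = FALSE) {
  strategy <- match.arg(strategy)
  assert_that(is_count(ratio_k) && ratio_k >= 1, "ratio_k must be >= 1")
  if (strategy == "matched") {
    assert_that(length(ps_covariates) > 0,
                "ps_covariates must be non-empty for matched selection")
  }
  structure(list(strategy = strategy, ratio_k = as.integer(ratio_k),
                 seed = as.integer(seed), ps_covariates = ps_covariates,
                 caliper = caliper,
                 case_order = match.arg(case_order),
                 passes = match.arg(passes),
                 allow_partial = isTRUE(allow_partial)),
            class = "selection_config")
}

new_study_design <- function(strategy, cases, controls, pairing = NULL,
                             seed = NA_integer_, ratio_k = NA_integer_) {
  assert_that(!any(controls %in% cases),
              "control ids must be disjoint from case ids")
  assert_that(!anyDuplicated(controls),
              "controls selected more than once (replacement is not allowed)")
  structure(list(strategy = strategy, cases = cases, controls = controls,
                 pairing = pairing, seed = seed, ratio_k = ratio_k),
            class = "study_design")
}

#' All-eligible-controls design
#'
#' @param cases Case sample ids.
#' @param pool Eligible control sample ids.
#' @return A `study_design` whose controls are the entire pool.
#' @export
select_all <- function(cases, pool) {
  assert_that(length(pool) > 0, "eligible control pool is empty")
  new_study_design("all", cases, pool)
}

#' Seeded random 1:k control selection
#'
#' Draws exactly `ratio_k * length(cases)` controls uniformly without
#' replacement using the configured seed; identical seeds give identical
#' selections. The caller's RNG state is untouched.
#'
#' @param cases Case sample ids.
#' @param pool Eligible control sample ids.
#' @param ratio_k Controls per case.
#' @param seed Integer seed (default 42).
#' @return A `study_design`.
#' @export
select_random <- function(cases, pool, ratio_k = 4L, seed = 42L) {
  need <- ratio_k * length(cases)
  if (length(pool) < need) {
    stop_ctrlgwas(sprintf(
      "control pool too small: %d required (%d cases x 1:%d), %d available",
      need, length(cases), ratio_k, length(pool)))
  }
  controls <- with_seed(seed, sample(pool, need))
  new_study_design("random", cases, controls, seed = as.integer(seed),
                   ratio_k = as.integer(ratio_k))
}

#' Propensity-score estimation
#'
#' Fits a case-versus-pool logistic regression of case status on the
#' configured covariates (categorical covariates expanded to indicator
#' contrasts with the most frequent level as reference) by iteratively
#' reweighted least squares (tolerance 1e-8, at most 50 iterations) and
#' returns the probability-scale score in (0, 1).
#'
#' @param samples Sample table containing cases and pool members.
#' @param ps_covariates Covariate names (default the 13).
#' @return Named numeric vector of propensity scores.
#' @export
estimate_propensity <- function(samples, ps_covariates = default_covariates()) {
  y <- as.numeric(samples$case_status == "case")
  X <- build_design_matrix(samples, ps_covariates)
  fit <- fit_logistic(y, X, tol = 1e-8, max_iter = 50L)
  if (!fit$converged) {
    if (fit$separated) {
      stop_ctrlgwas(paste0(
        "perfect separation in the propensity model; review the covariates ",
        "for one that identifies case status exactly"))
    }
    warning("propensity model did not converge in 50 iterations",
            call. = FALSE)
  }
  scores <- as.numeric(plogis(X %*% fit$coefficients))
  names(scores) <- samples$sample_id
  scores
}

#' Nearest-neighbour propensity matching without replacement
#'
#' Greedy matching: cases are processed in descending propensity order (or
#' data order), and each case takes its `ratio_k` nearest still-available
#' pool members by absolute probability-scale score difference. Exact
#' distance ties are broken by the smaller pool index (position in `pool`).
#' Matching is fully deterministic given the scores: no randomness is used.
#'
#' @param cases Case sample ids.
#' @param pool Eligible control sample ids.
#' @param scores Named propensity scores covering cases and pool.
#' @param config A [selection_config()] (fields `ratio_k`, `case_order`,
#'   `passes`, `caliper`, `allow_partial` are used).
#' @return A `study_design` with the case-to-controls pairing map.
#' @export
match_nearest <- function(cases, pool, scores,
                          config = selection_config("matched")) {
  k <- config$ratio_k
  if (!config$allow_partial && length(pool) < k * length(cases)) {
    stop_ctrlgwas(sprintf(
      "control pool too small for complete 1:%d matching: %d required, %d available",
      k, k * length(cases), length(pool)))
  }
  cs <- scores[cases]
  psc <- scores[pool]
  assert_that(!anyNA(cs) && !anyNA(psc),
              "scores must cover every case and pool member")
  ord_case <- switch(config$case_order,
                     descending = order(-cs, seq_along(cases)),
                     `data-order` = seq_along(cases))
  pairing <- rep(list(integer(0)), length(cases))
  names(pairing) <- cases
  st <- matcher_state(psc)
  rounds <- if (config$passes == "sequential") rep(1L, k) else k
  for (take in rounds) {
    for (ci in ord_case) {
      got <- matcher_take(st, cs[ci], take, config$caliper)
      pairing[[ci]] <- c(pairing[[ci]], got)
    }
  }
  short <- vapply(pairing, length, 0L) < k
  if (any(short) && !config$allow_partial) {
    stop_ctrlgwas(sprintf(
      "%d case(s) could not be given %d controls (pool exhausted or caliper)",
      sum(short), k))
  }
  pairing_ids <- lapply(pairing, function(ix) pool[ix])
  controls <- pool[unlist(pairing, use.names = FALSE)]
  new_study_design("matched", cases, controls, pairing = pairing_ids,
                   ratio_k = as.integer(k))
}

# Doubly-linked list over the score-sorted pool, supporting "take the k
# nearest available members to a query score" with deletion. Walks compress
# stale pointers so repeated queries stay near O(k).
matcher_state <- function(pool_scores) {
  m <- length(pool_scores)
  ord <- order(pool_scores, seq_len(m))
  e <- new.env(parent = emptyenv())
  e$score <- pool_scores[ord]       # sorted
  e$pidx <- ord                     # original pool index of sorted slot
  e$nxt <- c(seq_len(m)[-1L], m + 1L)
  e$prv <- c(0L, seq_len(m)[-m])
  e$alive <- rep(TRUE, m)
  e$m <- m
  e$n_alive <- m
  e
}

# next live slot at or after `i` (sorted index), with path compression
next_live <- function(e, i) {
  j <- i
  while (j <= e$m && !e$alive[j]) j <- e$nxt[j]
  if (i >= 1L && i <= e$m && j != i) e$nxt[i] <- min(j, e$m + 1L)
  j
}

prev_live <- function(e, i) {
  j <- i
  while (j >= 1L && !e$alive[j]) j <- e$prv[j]
  if (i >= 1L && i <= e$m && j != i) e$prv[i] <- max(j, 0L)
  j
}

# Remove slot j from the linked list.
matcher_drop <- function(e, j) {
  e$alive[j] <- FALSE
  e$n_alive <- e$n_alive - 1L
  p <- e$prv[j]; q <- e$nxt[j]
  if (p >= 1L) e$nxt[p] <- q
  if (q <= e$m) e$prv[q] <- p
}

# Take the `k` nearest available pool members to `x` (ties: smaller original
# pool index), honouring an optional caliper. Returns original pool indices.
matcher_take <- function(e, x, k, caliper = NULL) {
  if (e$n_alive == 0L) return(integer(0))
  r <- next_live(e, findInterval(x, e$score) + 1L)
  l <- prev_live(e, if (r > e$m) e$m else e$prv[r])
  if (l >= 1L && !e$alive[l]) l <- prev_live(e, l)
  cand_slot <- integer(0)
  cand_dist <- numeric(0)
  # expand two-pointer until k collected, then sweep remaining exact ties
  while (length(cand_slot) < k && (l >= 1L || r <= e$m)) {
    dl <- if (l >= 1L) abs(x - e$score[l]) else Inf
    dr <- if (r <= e$m) abs(e$score[r] - x) else Inf
    if (dl <= dr) {
      cand_slot <- c(cand_slot, l); cand_dist <- c(cand_dist, dl)
      l <- prev_live(e, e$prv[l])
    } else {
      cand_slot <- c(cand_slot, r); cand_dist <- c(cand_dist, dr)
      r <- next_live(e, e$nxt[r])
    }
  }
  if (!length(cand_slot)) return(integer(0))
  dmax <- max(cand_dist)
  while (l >= 1L && abs(x - e$score[l]) == dmax) {
    cand_slot <- c(cand_slot, l); cand_dist <- c(cand_dist, abs(x - e$score[l]))
    l <- prev_live(e, e$prv[l])
  }
  while (r <= e$m && abs(e$score[r] - x) == dmax) {
    cand_slot <- c(cand_slot, r); cand_dist <- c(cand_dist, abs(e$score[r] - x))
    r <- next_live(e, e$nxt[r])
  }
  if (!is.null(caliper)) {
    ok <- cand_dist <= caliper
    cand_slot <- cand_slot[ok]; cand_dist <- cand_dist[ok]
  }
  if (!length(cand_slot)) return(integer(0))
  sel <- order(cand_dist, e$pidx[cand_slot])[seq_len(min(k, length(cand_slot)))]
  chosen <- cand_slot[sel]
  for (j in chosen) matcher_drop(e, j)
  e$pidx[chosen]
}

#' Build a study design under a configured strategy
#'
#' Dispatcher over [select_all()], [select_random()] and the propensity
#' pipeline ([estimate_propensity()] + [match_nearest()]).
#'
#' @param samples Eligible sample table (cases plus control pool, e.g. from
#'   [eligible_pools()]).
#' @param config A [selection_config()].
#' @param scores Optional precomputed propensity scores (matched strategy).
#' @return A `study_design`.
#' @export
build_design <- function(samples, config, scores = NULL) {
  cases <- samples$sample_id[samples$case_status == "case"]
  pool <- samples$sample_id[samples$case_status == "control"]
  switch(config$strategy,
    all = select_all(cases, pool),
    random = select_random(cases, pool, config$ratio_k, config$seed),
    matched = {
      if (is.null(scores)) {
        scores <- estimate_propensity(samples, config$ps_covariates)
      }
      match_nearest(cases, pool, scores, config)
    })
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design [%s]: %d cases, %d controls (total %d)\n",
              x$strategy, length(x$cases), length(x$controls),
              length(x$cases) + length(x$controls)))
  if (!is.na(x$ratio_k)) cat(sprintf("  ratio 1:%d\n", x$ratio_k))
  if (!is.na(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
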