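# Independent oracles used to cross-check package implementations.
# These deliberately re-derive each quantity by the most direct route
# (full Newton steps, exhaustive pair enumeration, brute-force recounts)
# and share no code with the implementation paths they verify.

# Logistic regression by damped full Newton iterations on the log-likelihood.
newton_logistic <- function(y, X, tol = 1e-12, maxit = 200) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(H, grad)
    lik <- function(bb) {
      e <- drop(X %*% bb)
      sum(y * e - log1p(exp(e)))
    }
    l0 <- lik(b)
    s <- 1
    while (lik(b + s * step) < l0 && s > 1e-8) s <- s / 2
    b <- b + s * step
    if (max(abs(s * step)) < tol) break
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  H <- t(X) %*% (X * (mu * (1 - mu)))
  list(coefficients = b, vcov = solve(H))
}

# Hudson FST estimator, ratio of averages over variants, two populations.
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Plain quadratic-time greedy nearest-neighbour matcher: cases in descending
# score order, each scans the whole remaining pool for its k nearest by
# absolute score difference (ties: smaller pool index).
greedy_match_oracle <- function(case_scores, pool_scores, k) {
  avail <- rep(TRUE, length(pool_scores))
  pairing <- vector("list", length(case_scores))
  for (ci in order(-case_scores, seq_along(case_scores))) {
    d <- abs(pool_scores - case_scores[ci])
    ord <- order(!avail, d, seq_along(pool_scores))
    take <- head(ord[avail[ord]], k)
    pairing[[ci]] <- take
    avail[take] <- FALSE
  }
  pairing
}

# Transitive closure of the |dpos| <= window relation via union-find over
# all pairs (pair enumeration is exhaustive; instances up to ~1,000).
unionfind_clumps <- function(chrom, pos, window) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  close_pair <- outer(chrom, chrom, "==") &
    abs(outer(pos, pos, "-")) <= window
  ij <- which(close_pair & upper.tri(close_pair), arr.ind = TRUE)
  for (r in seq_len(nrow(ij))) {
    ri <- find(ij[r, 1]); rj <- find(ij[r, 2])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, 0L)
}

# Maximum number of within-window lead pairs by exhaustive recursion
# (small instances only).
max_pairs_bruteforce <- function(pos_a, chrom_a, pos_b, chrom_b, window) {
  recurse <- function(avail_a, avail_b) {
    best <- 0L
    for (i in avail_a) {
      for (j in avail_b) {
        if (chrom_a[i] == chrom_b[j] && abs(pos_a[i] - pos_b[j]) <= window) {
          best <- max(best, 1L + recurse(setdiff(avail_a, i),
                                         setdiff(avail_b, j)))
        }
      }
    }
    best
  }
  recurse(seq_along(pos_a), seq_along(pos_b))
}
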