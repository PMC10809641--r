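# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (loops, full enumeration, direct solves) so they
# never share code with the implementation paths they check.

# Ridge solution by direct penalized normal equations:
# (Xs'Xs + lambda * n * I) b = Xs'(y - ybar), features standardized to
# population SD.
oracle_ridge <- function(X, y, lambda) {
  n <- nrow(X)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2))
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  yc <- y - mean(y)
  A <- t(Xs) %*% Xs + lambda * n * diag(ncol(X))
  as.numeric(solve(A, t(Xs) %*% yc))
}

# Windowed pooled-count smoothing by explicit loops.
oracle_smooth <- function(meth, total, window) {
  h <- (window - 1) / 2
  n <- length(meth)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - h):min(n, i + h)
    out[i] <- sum(meth[idx]) / sum(total[idx])
  }
  out
}

# Enrichment score by all-prefix recomputation (O(N^2)).
oracle_es <- function(ranking, gene_set, exponent = 1) {
  hit <- ranking$gene %in% gene_set
  N <- nrow(ranking)
  w <- abs(ranking$weight)^exponent
  denom <- sum(w[hit])
  best <- 0
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(i)) {
      s <- s + if (hit[j]) {
        if (denom > 0) w[j] / denom else 1 / sum(hit)
      } else {
        -1 / (N - sum(hit))
      }
    }
    if (abs(s) > abs(best)) best <- s
  }
  best
}

# Exact two-sided rank-sum p by enumerating every group assignment.
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  w_null <- apply(combos, 2, function(idx) sum(ranks[idx]))
  p_lo <- mean(w_null <= w_obs)
  p_hi <- mean(w_null >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Two-sided Pearson p from the t closed form, written independently.
oracle_pearson_p <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * (1 - stats::pt(abs(tt), n - 2))
}

# Shared small fixtures -------------------------------------------------

tiny_cohort <- function(seed = 11, n_subjects = 60, n_cpgs = 400,
                        n_lmrs = 15, n_signal = 30, ...) {
  simulate_cohort(sim_config(n_subjects = n_subjects, n_cpgs = n_cpgs,
                             n_lmrs = n_lmrs, n_signal_features = n_signal,
                             seed = seed, ...))
}

toy_ranking <- function(n = 10, seed = 1) {
  set.seed(seed)
  ranked_gene_list(sprintf("g%02d", seq_len(n)),
                   sort(rnorm(n), decreasing = TRUE))
}

# Minimal hand-built clock model for predict() tests.
manual_clock <- function(ids, coef, means, sds, intercept,
                         kind = "visual_age", level = "cpg") {
  structure(list(outcome_kind = kind, feature_level = level,
                 feature_ids = ids,
                 intercept = intercept,
                 coefficients = stats::setNames(coef, ids),
                 feature_means = stats::setNames(means, ids),
                 feature_sds = stats::setNames(sds, ids),
                 alpha = 0, lambda = 0,
                 dropped_features = character(0)),
            class = "clock_model")
}
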