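# Clock validation statistics: MAE, Pearson correlation tests, and
# Wilcoxon rank-sum group discrimination (exact by enumeration when
# feasible, otherwise normal approximation with tie and continuity
# corrections).

#' Mean absolute error
#' @param pred,obs Equal-length numeric vectors.
#' @return Mean of `|pred - obs|`.
#' @export
mae <- function(pred, obs) {
  if (length(pred) != length(obs)) data_error("length mismatch in mae()")
  if (length(pred) == 0L) data_error("mae() needs at least one value")
  mean(abs(pred - obs))
}

#' Pearson correlation with a two-sided t test
#'
#' p is computed from `t = r * sqrt((n - 2) / (1 - r^2))` against the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 3, neither constant.
#' @return List with `r`, `statistic`, `df`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) data_error("length mismatch in pearson_test()")
  n <- length(x)
  if (n < 3L) data_error("pearson_test() needs n >= 3")
  if (pop_sd(x) == 0 || pop_sd(y) == 0) {
    skinclock_error("correlation undefined for constant input",
                    "skinclock_statistic_error")
  }
  r <- stats::cor(x, y)
  tstat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  list(r = r, statistic = tstat, df = n - 2L,
       p_value = 2 * stats::pt(-abs(tstat), n - 2L), n = n)
}

# Exact null distribution of the rank-sum W of a size-m group drawn from
# tie-free pooled ranks 1..N: counts[w + 1] = #subsets of size m summing
# to w, by subset-sum dynamic programming.
ranksum_null_counts <- function(m, N) {
  wmax <- (N * (N + 1L)) %/% 2L
  dp <- matrix(0, nrow = m + 1L, ncol = wmax + 1L)
  dp[1L, 1L] <- 1
  for (r in seq_len(N)) {
    smax <- min(m, r)
    for (s in smax:1L) {
      cols <- (r + 1L):(wmax + 1L)
      dp[s + 1L, cols] <- dp[s + 1L, cols] + dp[s, cols - r]
    }
  }
  dp[m + 1L, ]
}

#' Wilcoxon rank-sum test for two groups
#'
#' Uses the exact permutation distribution (full enumeration over group
#' assignments) when both groups have at most `exact_threshold`
#' observations and the pooled data are tie-free; otherwise a normal
#' approximation with tie correction and continuity correction. Two-sided
#' p = min(1, 2 x one-sided).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_threshold Maximum per-group size for the exact method
#'   (default 25).
#' @param group_labels Length-2 character labels for reporting.
#' @return List with `group_labels`, `n_per_group`,
#'   `rank_sum_statistic` (rank sum of `a` on pooled mid-ranks),
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_threshold = 25L,
                              group_labels = c("a", "b")) {
  if (length(a) == 0L || length(b) == 0L) {
    data_error("both groups must be non-empty")
  }
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  pooled <- c(a, b)
  ranks <- rank(pooled)
  W <- sum(ranks[seq_len(n_a)])
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n_a <= exact_threshold && n_b <= exact_threshold) {
    counts <- ranksum_null_counts(n_a, N)
    total <- sum(counts)
    p_lo <- sum(counts[seq_len(W + 1L)]) / total
    p_hi <- sum(counts[(W + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n_a * (N + 1) / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
      if (W == mu) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(group_labels = group_labels,
                 n_per_group = c(n_a, n_b),
                 rank_sum_statistic = W,
                 p_value = p,
                 method = method),
            class = "group_comparison")
}

#' Predicted progression from visual-age predictions
#'
#' The predicted progression is the elementwise difference between the
#' predicted visual facial age and the chronological age.
#'
#' @param predicted_visual_age,chronological_age Equal-length vectors.
#' @return Numeric vector of predicted progression (years).
#' @export
progression_from_predictions <- function(predicted_visual_age,
                                         chronological_age) {
  if (length(predicted_visual_age) != length(chronological_age)) {
    data_error("length mismatch in progression_from_predictions()")
  }
  predicted_visual_age - chronological_age
}

#' Validate a clock on a labelled dataset
#'
#' Derives the observed outcome via [make_outcome()], predicts via
#' [predict.clock_model()], and reports MAE plus the Pearson test. For
#' progression clocks the correlation of predictions with chronological
#' age is reported as a secondary diagnostic. Constant predictions are
#' flagged rather than producing an undefined correlation.
#'
#' @param model A `clock_model`.
#' @param beta Beta matrix at the model's feature level.
#' @param phenotypes Phenotype table covering the beta samples.
#' @param dataset_label Free-text label stored in the report.
#' @return A `validation_report` list.
#' @export
validate_clock <- function(model, beta, phenotypes,
                           dataset_label = "test") {
  preds <- stats::predict(model, beta)
  obs_all <- make_outcome(phenotypes, model$outcome_kind)
  missing <- setdiff(names(preds), names(obs_all))
  if (length(missing) > 0L) {
    data_error(sprintf("phenotypes lack %d beta samples (e.g. %s)",
                       length(missing), missing[1]))
  }
  obs <- obs_all[names(preds)]
  report <- list(n = length(preds),
                 mae = mae(preds, obs),
                 pearson_r = NA_real_,
                 p_value = NA_real_,
                 outcome_kind = model$outcome_kind,
                 dataset = dataset_label,
                 constant_prediction = pop_sd(preds) == 0)
  if (!report$constant_prediction) {
    pt <- pearson_test(preds, obs)
    report$pearson_r <- pt$r
    report$p_value <- pt$p_value
  }
  if (model$outcome_kind == "progression" && !report$constant_prediction) {
    if (!"chronological_age" %in% names(phenotypes)) {
      data_error("progression diagnostic needs `chronological_age`")
    }
    age <- stats::setNames(phenotypes$chronological_age,
                           phenotypes$sample_id)[names(preds)]
    report$r_with_chronological_age <- pearson_test(preds, age)$r
  }
  structure(report, class = "validation_report")
}

#' Write a validation report as JSON and TSV
#' @param report A `validation_report`.
#' @param path Output path without extension; writes `path.json` and
#'   `path.tsv`.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  flat <- unclass(report)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  utils::write.table(as.data.frame(flat), paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
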