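# Ridge-regression epigenetic clocks.
#
# Convention: features are standardized to mean 0 and population SD 1;
# the intercept (mean outcome) is unpenalized; coefficients solve
# (Xs'Xs + lambda * n * I) b = Xs'(y - ybar). Printed lambda values are
# therefore tied to this scaling and to the data, never portable across
# conventions.

#' Stratified train/test partition
#'
#' Samples are binned by outcome quantiles into `n_bins` groups; within
#' each bin a seed-determined draw allocates members to the training set
#' so that the total training size is exactly `floor(p * n)` and each
#' bin's train fraction deviates from `p` by at most one sample.
#'
#' @param outcome Per-sample outcome (names become sample ids).
#' @param p Train fraction in (0, 1), default 0.8.
#' @param n_bins Number of quantile strata (default 10).
#' @param seed Integer seed.
#' @return List with `train_ids`, `test_ids`, `p`, `n_bins`, `seed`.
#' @export
stratified_partition <- function(outcome, p = 0.8, n_bins = 10L, seed = 1L) {
  n <- length(outcome)
  n_bins <- as.integer(n_bins)
  if (p <= 0 || p >= 1) config_error("`p` must be in (0, 1)")
  if (n_bins < 1L || n_bins > n) {
    config_error("`n_bins` must satisfy 1 <= n_bins <= n")
  }
  ids <- names(outcome) %||% as.character(seq_len(n))
  brk <- unique(stats::quantile(outcome, seq(0, 1, length.out = n_bins + 1L),
                                names = FALSE))
  bins <- if (length(brk) < 2L) rep(1L, n) else {
    cut(outcome, brk, include.lowest = TRUE, labels = FALSE)
  }
  target <- floor(p * n)
  n_b <- tabulate(bins)
  base <- floor(p * n_b)
  extra <- target - sum(base)
  train <- with_seed(seed, {
    alloc <- base
    if (extra > 0L) {
      rem <- p * n_b - base
      elig <- which(rem > 1e-9)
      bump <- elig[sample.int(length(elig), extra, prob = rem[elig])]
      alloc[bump] <- alloc[bump] + 1L
    }
    unlist(lapply(seq_along(n_b), function(b) {
      members <- which(bins == b)
      members[sample.int(length(members), alloc[b])]
    }), use.names = FALSE)
  })
  train <- sort(train)
  structure(list(train_ids = ids[train],
                 test_ids = ids[setdiff(seq_len(n), train)],
                 p = p, n_bins = n_bins, seed = as.integer(seed)),
            class = "partition")
}

# SVD-based ridge solve on a pre-standardized matrix. Returns the
# coefficient matrix (features x length(lambdas)) under the package's
# penalty convention; rank-deficient directions fall back to the
# minimum-norm solution.
ridge_coef_path <- function(Xs, yc, lambdas) {
  n <- nrow(Xs)
  sv <- svd(Xs)
  d <- sv$d
  tol <- max(d) * 1e-12
  z <- as.numeric(crossprod(sv$u, yc))
  f <- vapply(lambdas, function(l) {
    if (l == 0) ifelse(d > tol, 1 / d, 0) else d / (d^2 + l * n)
  }, numeric(length(d)))
  sv$v %*% (matrix(f, ncol = length(lambdas)) * z)
}

standardize_features <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2L, pop_sd)
  keep <- sds > 0
  list(Xs = sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                  sds[keep], "/"),
       means = mu[keep], sds = sds[keep],
       dropped = colnames(X)[!keep])
}

#' Fit a ridge clock at a fixed penalty
#'
#' @param X Samples x features numeric matrix (no missing values).
#' @param y Outcome vector.
#' @param lambda Penalty (>= 0).
#' @param outcome_kind One of `"wrinkle_grade"`, `"visual_age"`,
#'   `"progression"`.
#' @param feature_level `"cpg"` or `"lmr"`.
#' @return A `clock_model`: intercept, per-feature coefficients on the
#'   standardized scale, standardization parameters, `alpha = 0`, and
#'   `lambda`. Zero-variance features are dropped and recorded in
#'   `dropped_features`.
#' @export
ridge_fit <- function(X, y, lambda,
                      outcome_kind = c("visual_age", "wrinkle_grade",
                                       "progression"),
                      feature_level = c("cpg", "lmr")) {
  outcome_kind <- match.arg(outcome_kind)
  feature_level <- match.arg(feature_level)
  if (anyNA(X) || anyNA(y)) data_error("missing values in training data")
  if (nrow(X) < 2L) data_error("need at least 2 samples")
  if (length(y) != nrow(X)) data_error("length(y) must equal nrow(X)")
  if (lambda < 0) config_error("`lambda` must be >= 0")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%05d", seq_len(ncol(X)))
  std <- standardize_features(X)
  if (ncol(std$Xs) == 0L) model_error("all features have zero variance")
  yc <- y - mean(y)
  coef <- as.numeric(ridge_coef_path(std$Xs, yc, lambda))
  names(coef) <- colnames(std$Xs)
  structure(list(outcome_kind = outcome_kind,
                 feature_level = feature_level,
                 feature_ids = colnames(std$Xs),
                 intercept = mean(y),
                 coefficients = coef,
                 feature_means = std$means,
                 feature_sds = std$sds,
                 alpha = 0,
                 lambda = lambda,
                 dropped_features = std$dropped),
            class = "clock_model")
}

#' Geometric lambda path
#'
#' Builds a decreasing geometric penalty sequence of length `n_lambda`
#' from `lambda_max` down to `lambda_max * ratio`, where `lambda_max` is
#' grown until the largest standardized coefficient magnitude falls below
#' 1e-3 of its unpenalized value.
#'
#' @param X Samples x features matrix.
#' @param y Outcome vector (must not be constant).
#' @param n_lambda Path length (default 100).
#' @param ratio Terminal ratio `lambda_min / lambda_max` (default 1e-9, so
#'   the path spans from an effectively null model to an effectively
#'   unpenalized one).
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(X, y, n_lambda = 100L, ratio = 1e-9) {
  if (n_lambda < 2L) config_error("`n_lambda` must be >= 2")
  if (ratio <= 0 || ratio >= 1) config_error("`ratio` must be in (0, 1)")
  if (pop_sd(y) == 0) model_error("constant outcome: lambda path undefined")
  std <- standardize_features(X)
  if (ncol(std$Xs) == 0L) model_error("all features have zero variance")
  yc <- y - mean(y)
  b0 <- abs(as.numeric(ridge_coef_path(std$Xs, yc, 0)))
  m0 <- max(b0)
  if (m0 == 0) model_error("outcome orthogonal to all features")
  lam <- max(svd(std$Xs)$d)^2 / nrow(std$Xs)
  for (i in 1:200) {
    b <- abs(as.numeric(ridge_coef_path(std$Xs, yc, lam)))
    if (max(b) < 1e-3 * m0) break
    lam <- lam * 2
  }
  lam * ratio^seq(0, 1, length.out = n_lambda)
}

#' Cross-validated ridge clock training
#'
#' Seed-determined k-fold assignment (fold sizes differ by at most one);
#' per lambda and fold, the mean absolute error on the held-out fold is
#' recorded. The selected lambda minimizes the mean CV MAE, with ties
#' resolved towards the larger penalty; the final model is refit on all
#' training data at that lambda.
#'
#' @param X Samples x features matrix.
#' @param y Outcome vector.
#' @param k Number of folds (default 10).
#' @param lambda_grid Decreasing penalties; computed by [lambda_path()]
#'   when `NULL`.
#' @param seed Integer seed for the fold assignment.
#' @param outcome_kind,feature_level Stored on the refit model.
#' @return List with `model` (the refit [ridge_fit()] clock) and `cv`
#'   (lambda grid, per-fold MAE matrix, mean/SD MAE, selected lambda,
#'   fold assignments).
#' @export
cv_train <- function(X, y, k = 10L, lambda_grid = NULL, seed = 1L,
                     outcome_kind = c("visual_age", "wrinkle_grade",
                                      "progression"),
                     feature_level = c("cpg", "lmr")) {
  outcome_kind <- match.arg(outcome_kind)
  feature_level <- match.arg(feature_level)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 2L || k > n) config_error("need 2 <= k <= n samples")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%05d", seq_len(ncol(X)))
  grid <- lambda_grid %||% lambda_path(X, y)
  if (is.unsorted(rev(grid))) {
    config_error("`lambda_grid` must be decreasing")
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  fold_mae <- matrix(NA_real_, nrow = k, ncol = length(grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (pop_sd(y[tr]) == 0) {
      # constant training outcome: predict its mean everywhere
      fold_mae[f, ] <- mean(abs(y[!tr] - mean(y[tr])))
      next
    }
    std <- standardize_features(X[tr, , drop = FALSE])
    B <- ridge_coef_path(std$Xs, y[tr] - mean(y[tr]), grid)
    Xte <- sweep(sweep(X[!tr, names(std$means), drop = FALSE], 2L,
                       std$means), 2L, std$sds, "/")
    preds <- Xte %*% B + mean(y[tr])
    fold_mae[f, ] <- colMeans(abs(preds - y[!tr]))
  }
  mean_mae <- colMeans(fold_mae)
  sd_mae <- apply(fold_mae, 2L, stats::sd)
  sel <- which.min(mean_mae)  # grid decreasing: first minimum = largest lambda
  model <- ridge_fit(X, y, grid[sel], outcome_kind, feature_level)
  cv <- structure(list(lambda_grid = grid, fold_mae = fold_mae,
                       mean_mae = mean_mae, sd_mae = sd_mae,
                       selected_lambda = grid[sel],
                       fold_assignments = stats::setNames(folds,
                                                          rownames(X))),
                  class = "cv_result")
  list(model = model, cv = cv)
}

#' Derive the outcome vector from a phenotype table
#'
#' `wrinkle_grade` and `visual_age` are the panel means; `progression` is
#' visual age minus chronological age.
#'
#' @param phenotypes Phenotype data.frame with `sample_id`,
#'   `chronological_age`, `wrinkle_grade`, `visual_age`.
#' @param kind Outcome kind.
#' @return Named numeric vector (names = sample ids).
#' @export
make_outcome <- function(phenotypes,
                         kind = c("wrinkle_grade", "visual_age",
                                  "progression")) {
  kind <- match.arg(kind)
  need <- switch(kind,
                 wrinkle_grade = "wrinkle_grade",
                 visual_age = "visual_age",
                 progression = c("visual_age", "chronological_age"))
  missing <- setdiff(c("sample_id", need), names(phenotypes))
  if (length(missing) > 0L) {
    data_error(sprintf("phenotype table lacks columns: %s",
                       paste(missing, collapse = ", ")))
  }
  out <- switch(kind,
                wrinkle_grade = phenotypes$wrinkle_grade,
                visual_age = phenotypes$visual_age,
                progression = phenotypes$visual_age -
                  phenotypes$chronological_age)
  stats::setNames(out, phenotypes$sample_id)
}

#' Predict from a trained clock
#'
#' @param object A `clock_model`.
#' @param beta Beta matrix (features x samples) containing every model
#'   feature at the matching level; missing features raise an error, never
#'   silent imputation.
#' @param ... Unused.
#' @return Named per-sample predictions in outcome units.
#' @export
predict.clock_model <- function(object, beta, ...) {
  lvl <- feature_level(beta)
  if (!is.null(lvl) && !identical(lvl, object$feature_level)) {
    data_error(sprintf("beta is at %s level but the clock expects %s",
                       lvl, object$feature_level))
  }
  missing <- setdiff(object$feature_ids, rownames(beta))
  if (length(missing) > 0L) {
    data_error(sprintf("beta lacks %d model features: %s%s",
                       length(missing),
                       paste(utils::head(missing, 5), collapse = ", "),
                       if (length(missing) > 5) ", ..." else ""))
  }
  X <- t(beta[object$feature_ids, , drop = FALSE])
  Xs <- sweep(sweep(X, 2L, object$feature_means), 2L, object$feature_sds,
              "/")
  stats::setNames(as.numeric(object$intercept + Xs %*% object$coefficients),
                  colnames(beta))
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s clock (%s level)\n", x$outcome_kind,
              x$feature_level))
  cat(sprintf("  features: %d  lambda: %.6g  alpha: 0\n",
              length(x$feature_ids), x$lambda))
  invisible(x)
}

#' Serialize / restore a clock model as JSON
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @param provenance Optional list (e.g. config hash, seed) stored
#'   verbatim.
#' @export
write_clock_model <- function(model, path, provenance = NULL) {
  payload <- unclass(model)
  payload$provenance <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.character(p$feature_ids)
  structure(list(outcome_kind = p$outcome_kind,
                 feature_level = p$feature_level,
                 feature_ids = ids,
                 intercept = as.numeric(p$intercept),
                 coefficients = stats::setNames(as.numeric(p$coefficients),
                                                ids),
                 feature_means = stats::setNames(as.numeric(p$feature_means),
                                                 ids),
                 feature_sds = stats::setNames(as.numeric(p$feature_sds),
                                               ids),
                 alpha = 0,
                 lambda = as.numeric(p$lambda),
                 dropped_features = as.character(p$dropped_features %||%
                                                   character(0)),
                 provenance = p$provenance),
            class = "clock_model")
}

#' Write a CV report TSV (lambda, per-fold MAE, mean, SD)
#' @param cv A `cv_result`.
#' @param path Output path.
#' @export
write_cv_report <- function(cv, path) {
  k <- nrow(cv$fold_mae)
  df <- data.frame(lambda = cv$lambda_grid, t(cv$fold_mae),
                   mean_mae = cv$mean_mae, sd_mae = cv$sd_mae)
  names(df)[2:(k + 1L)] <- sprintf("fold%02d_mae", seq_len(k))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
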