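#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so library functions never perturb user-level
#' reproducibility.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    config_error("`seed` must be a single finite integer")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific child seed from a base seed. Double-precision
# arithmetic avoids 32-bit overflow; the modulus keeps the result a valid
# R integer seed.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 31 + as.numeric(stream)) %% 2147483587)
}

#' Construct a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with features (CpGs or LMRs) as
#' rows and samples as columns, values in \[0, 1\], and a `feature_level`
#' attribute.
#'
#' @param values Numeric matrix, rows = features, columns = samples.
#' @param feature_level Either `"cpg"` or `"lmr"`.
#' @return The validated matrix with attribute `feature_level`.
#' @export
beta_matrix <- function(values, feature_level = c("cpg", "lmr")) {
  feature_level <- match.arg(feature_level)
  if (!is.matrix(values) || !is.numeric(values)) {
    data_error("beta matrix must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    data_error("beta matrix needs feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    data_error("beta matrix feature ids must be unique")
  }
  if (anyNA(values)) data_error("beta matrix contains missing values")
  if (any(values < 0 | values > 1)) {
    data_error("beta values must lie in [0, 1]")
  }
  attr(values, "feature_level") <- feature_level
  values
}

#' Feature level of a beta matrix
#' @param x A matrix created by [beta_matrix()].
#' @return `"cpg"`, `"lmr"`, or `NULL` when unset.
#' @export
feature_level <- function(x) attr(x, "feature_level", exact = TRUE)

# Population standard deviation (divide by n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
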