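# Synthetic cohort generator
#
# Emulates the statistical structure of a panel-rated skin-aging
# methylation study: a beta-value matrix with planted low-methylated
# regions (LMRs) and progression-linked CpGs, multi-rater phenotype noise,
# WGBS-like counts, and expression correlated with age progression.

#' Simulation configuration
#'
#' Holds every knob of the synthetic cohort. Defaults encode the study
#' design being emulated: 378 subjects aged 29-84, a ~30-expert rating
#' panel with per-subject rating SDs near 11.85 (wrinkle scale) and 6.55
#' years (visual age), and ~14x WGBS coverage.
#'
#' @param n_subjects Number of subjects.
#' @param n_cpgs Number of CpGs on the synthetic array.
#' @param n_lmrs Number of planted low-methylated regions.
#' @param lmr_cpg_range Length-2 integer vector: min/max CpGs per planted LMR.
#' @param n_signal_features Number of CpGs (all inside planted LMRs) whose
#'   beta is linearly shifted by `effect_size * true_progression`.
#' @param effect_size Beta units per year of progression.
#' @param age_range Length-2 numeric: chronological age range in years.
#' @param progression_sd SD (years) of true visual age progression.
#' @param age_coupling Regression slope of progression on centred age;
#'   0 (default) makes progression independent of chronological age.
#' @param rater_count Panel size.
#' @param rater_sd_wrinkle Per-rater SD on the 1-100 wrinkle scale.
#' @param rater_sd_age Per-rater SD in years for visual age.
#' @param wgbs_mean_coverage Mean WGBS read depth per CpG.
#' @param beta_noise_sd SD of (truncated) Gaussian beta noise.
#' @param wrinkle_intercept,wrinkle_slope,wrinkle_noise_sd Affine map from
#'   true visual age to true wrinkle grade, plus its noise SD.
#' @param n_chroms Number of synthetic chromosomes.
#' @param seed Integer seed; fully determines all outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 378L,
                       n_cpgs = 2000L,
                       n_lmrs = 60L,
                       lmr_cpg_range = c(5L, 10L),
                       n_signal_features = 50L,
                       effect_size = 0.005,
                       age_range = c(29, 84),
                       progression_sd = 5,
                       age_coupling = 0,
                       rater_count = 30L,
                       rater_sd_wrinkle = 11.85,
                       rater_sd_age = 6.55,
                       wgbs_mean_coverage = 14,
                       beta_noise_sd = 0.02,
                       wrinkle_intercept = -20,
                       wrinkle_slope = 1.2,
                       wrinkle_noise_sd = 5,
                       n_chroms = 2L,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_cpgs = as.integer(n_cpgs),
              n_lmrs = as.integer(n_lmrs),
              lmr_cpg_range = as.integer(lmr_cpg_range),
              n_signal_features = as.integer(n_signal_features),
              effect_size = effect_size,
              age_range = as.numeric(age_range),
              progression_sd = progression_sd,
              age_coupling = age_coupling,
              rater_count = as.integer(rater_count),
              rater_sd_wrinkle = rater_sd_wrinkle,
              rater_sd_age = rater_sd_age,
              wgbs_mean_coverage = wgbs_mean_coverage,
              beta_noise_sd = beta_noise_sd,
              wrinkle_intercept = wrinkle_intercept,
              wrinkle_slope = wrinkle_slope,
              wrinkle_noise_sd = wrinkle_noise_sd,
              n_chroms = as.integer(n_chroms),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_subjects", "n_cpgs", "n_lmrs", "rater_count", "n_chroms")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      config_error(sprintf("`%s` must be a positive count", f))
    }
  }
  if (cfg$n_signal_features < 0L) {
    config_error("`n_signal_features` must be >= 0")
  }
  if (length(cfg$lmr_cpg_range) != 2L ||
      cfg$lmr_cpg_range[1] < 1L ||
      cfg$lmr_cpg_range[1] > cfg$lmr_cpg_range[2]) {
    config_error("`lmr_cpg_range` must be (min, max) with 1 <= min <= max")
  }
  if (cfg$age_range[1] >= cfg$age_range[2]) {
    config_error("`age_range` must have min < max")
  }
  if (cfg$rater_sd_wrinkle < 0 || cfg$rater_sd_age < 0) {
    config_error("rater SDs must be >= 0")
  }
  if (cfg$wgbs_mean_coverage <= 0) {
    config_error("`wgbs_mean_coverage` must be > 0")
  }
  if (cfg$beta_noise_sd < 0) config_error("`beta_noise_sd` must be >= 0")
  if (cfg$progression_sd < 0) config_error("`progression_sd` must be >= 0")
  if (cfg$n_signal_features > cfg$n_lmrs * cfg$lmr_cpg_range[2]) {
    config_error("`n_signal_features` exceeds the maximum number of LMR CpGs")
  }
  invisible(cfg)
}

# Lay out CpG positions and planted LMR runs on synthetic chromosomes.
# Returns per-CpG chrom/pos plus the run index (0 = background).
plant_genome <- function(cfg) {
  n_per <- diff(floor(seq(0, cfg$n_cpgs, length.out = cfg$n_chroms + 1L)))
  lmr_per <- diff(floor(seq(0, cfg$n_lmrs, length.out = cfg$n_chroms + 1L)))
  chrom <- character(0); pos <- integer(0); run <- integer(0)
  next_run <- 1L
  for (ci in seq_len(cfg$n_chroms)) {
    npos <- n_per[ci]
    if (npos == 0L) next
    nl <- lmr_per[ci]
    lens <- if (nl > 0L) {
      sample(seq(cfg$lmr_cpg_range[1], cfg$lmr_cpg_range[2]), nl,
             replace = TRUE)
    } else integer(0)
    need <- sum(lens) + 2L * (nl + 1L)
    if (npos < need) {
      config_error(sprintf(
        "chromosome %d has %d CpGs but planted LMRs need >= %d", ci, npos,
        need))
    }
    slack <- npos - need
    extra <- as.integer(stats::rmultinom(1L, slack, rep(1, nl + 1L)))
    gaps <- 2L + extra
    run_c <- integer(npos)
    idx <- 0L
    for (li in seq_len(nl)) {
      idx <- idx + gaps[li]
      run_c[(idx + 1L):(idx + lens[li])] <- next_run
      next_run <- next_run + 1L
      idx <- idx + lens[li]
    }
    gap_bp <- sample(20:200, npos, replace = TRUE)
    pos_c <- cumsum(gap_bp) + 1000L
    chrom <- c(chrom, rep(paste0("chr", ci), npos))
    pos <- c(pos, pos_c)
    run <- c(run, run_c)
  }
  list(chrom = chrom, pos = pos, run = run)
}

#' Simulate a full synthetic cohort
#'
#' Generates a beta matrix with planted LMRs (baseline beta < 0.3 inside,
#' > 0.6 outside), exactly `n_signal_features` LMR CpGs whose mean beta
#' shifts by `effect_size` per year of true progression, a CpG manifest
#' with 0-2 gene symbols per CpG, panel-rated phenotypes, and the
#' generating truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements `beta` (CpG-level beta matrix),
#'   `phenotypes` (data.frame: `sample_id`, `chronological_age`,
#'   `wrinkle_grade`, `visual_age`, plus per-subject rating SDs),
#'   `manifest`, and `truth` (chronological age, true progression, true
#'   visual age, true wrinkle, signal feature ids, planted LMR regions).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_subjects
    sample_ids <- sprintf("S%04d", seq_len(n))

    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    prog <- stats::rnorm(n, 0, config$progression_sd) +
      config$age_coupling * (age - mean(age))
    visual <- age + prog
    prog <- visual - age  # re-derive so visual - age == prog bit-exactly
    wrinkle <- clip(config$wrinkle_intercept +
                      config$wrinkle_slope * visual +
                      stats::rnorm(n, 0, config$wrinkle_noise_sd), 1, 100)

    geno <- plant_genome(config)
    cpg_ids <- sprintf("cg%07d", seq_len(config$n_cpgs))
    in_lmr <- geno$run > 0L

    n_lmr_cpgs <- sum(in_lmr)
    if (config$n_signal_features > n_lmr_cpgs) {
      config_error(sprintf(
        "n_signal_features (%d) exceeds the %d CpGs inside planted LMRs",
        config$n_signal_features, n_lmr_cpgs))
    }

    baseline <- numeric(config$n_cpgs)
    baseline[in_lmr] <- stats::runif(n_lmr_cpgs, 0.05, 0.25)
    baseline[!in_lmr] <- stats::runif(config$n_cpgs - n_lmr_cpgs, 0.65, 0.95)

    # Signal CpGs fill whole LMRs (in seeded random order) so that
    # region-averaged features carry the planted progression signal.
    signal <- logical(config$n_cpgs)
    if (config$n_signal_features > 0L) {
      lmr_order <- sample(seq_len(config$n_lmrs))
      remaining <- config$n_signal_features
      for (li in lmr_order) {
        members <- which(geno$run == li)
        take <- min(length(members), remaining)
        signal[members[seq_len(take)]] <- TRUE
        remaining <- remaining - take
        if (remaining == 0L) break
      }
    }

    m <- matrix(baseline, nrow = config$n_cpgs, ncol = n)
    if (config$effect_size != 0) {
      m <- m + (as.numeric(signal) * config$effect_size) %o% prog
    }
    if (config$beta_noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, config$beta_noise_sd),
                      nrow = nrow(m))
    }
    m <- clip(m, 0, 1)
    rownames(m) <- cpg_ids
    colnames(m) <- sample_ids
    beta <- beta_matrix(m, "cpg")

    gene_pool <- sprintf("GENE%04d", seq_len(max(100L, config$n_cpgs %/% 10L)))
    n_genes_per <- sample(0:2, config$n_cpgs, replace = TRUE,
                          prob = c(0.2, 0.6, 0.2))
    gene <- vapply(n_genes_per, function(k) {
      if (k == 0L) "" else paste(sample(gene_pool, k), collapse = ",")
    }, character(1))
    manifest <- data.frame(cpg_id = cpg_ids, chrom = geno$chrom,
                           pos = geno$pos, gene = gene,
                           stringsAsFactors = FALSE)

    planted <- do.call(rbind, lapply(seq_len(config$n_lmrs), function(li) {
      members <- which(geno$run == li)
      data.frame(chrom = geno$chrom[members[1]],
                 start = geno$pos[members[1]],
                 end = geno$pos[members[length(members)]] + 1L,
                 n_cpgs = length(members),
                 mean_methylation = mean(baseline[members]),
                 class = "LMR", stringsAsFactors = FALSE)
    }))
    planted <- region_set(planted$chrom, planted$start, planted$end,
                          planted$n_cpgs, planted$mean_methylation,
                          planted$class)

    wr <- simulate_panel_ratings(wrinkle, config$rater_count,
                                 config$rater_sd_wrinkle,
                                 seed = child_seed(config$seed, 1L),
                                 scale = "wrinkle")
    va <- simulate_panel_ratings(visual, config$rater_count,
                                 config$rater_sd_age,
                                 seed = child_seed(config$seed, 2L))

    phenotypes <- data.frame(sample_id = sample_ids,
                             chronological_age = age,
                             wrinkle_grade = wr$mean,
                             visual_age = va$mean,
                             wrinkle_rating_sd = wr$sd,
                             visual_age_rating_sd = va$sd,
                             stringsAsFactors = FALSE)

    truth <- list(chronological_age = stats::setNames(age, sample_ids),
                  true_progression = stats::setNames(prog, sample_ids),
                  true_visual_age = stats::setNames(visual, sample_ids),
                  true_wrinkle = stats::setNames(wrinkle, sample_ids),
                  signal_feature_ids = cpg_ids[signal],
                  planted_lmr_regions = planted)

    list(beta = beta, phenotypes = phenotypes, manifest = manifest,
         truth = truth)
  })
}

#' Simulate an expert rating panel
#'
#' Each of `rater_count` raters scores each subject as truth plus
#' independent Gaussian noise; the reported phenotype is the across-rater
#' mean. On the wrinkle scale individual ratings are clipped to \[1, 100\]
#' before averaging.
#'
#' @param truth Per-subject true value.
#' @param rater_count Number of raters (>= 1).
#' @param rater_sd Per-rater noise SD (>= 0).
#' @param seed Integer seed.
#' @param scale `"none"` or `"wrinkle"` (clip ratings to \[1, 100\]).
#' @return List with `ratings` (subjects x raters matrix), `mean`, `sd`
#'   (per-subject across-rater mean and SD).
#' @export
simulate_panel_ratings <- function(truth, rater_count = 30L, rater_sd,
                                   seed = 1L, scale = c("none", "wrinkle")) {
  scale <- match.arg(scale)
  rater_count <- as.integer(rater_count)
  if (is.na(rater_count) || rater_count < 1L) {
    config_error("`rater_count` must be >= 1")
  }
  if (rater_sd < 0) config_error("`rater_sd` must be >= 0")
  with_seed(seed, {
    n <- length(truth)
    ratings <- matrix(rep(truth, times = rater_count), nrow = n) +
      matrix(stats::rnorm(n * rater_count, 0, rater_sd), nrow = n)
    if (scale == "wrinkle") ratings <- clip(ratings, 1, 100)
    rownames(ratings) <- names(truth)
    list(ratings = ratings,
         mean = rowMeans(ratings),
         sd = apply(ratings, 1L, stats::sd))
  })
}

#' Simulate WGBS-like methylation counts
#'
#' Per-CpG total counts are Poisson with the stated mean coverage;
#' methylated counts are binomial given the CpG's true methylation (low
#' inside planted LMRs). CpGs drawing zero coverage are omitted.
#'
#' @param planted_lmrs Region set of planted LMRs.
#' @param manifest CpG manifest (0-based `pos`).
#' @param mean_coverage Mean read depth (> 0), default 14.
#' @param seed Integer seed.
#' @param lmr_level,background_level True methylation inside / outside
#'   planted LMRs.
#' @return A `wgbs_methylome`.
#' @export
simulate_wgbs <- function(planted_lmrs, manifest, mean_coverage = 14,
                          seed = 1L, lmr_level = 0.15,
                          background_level = 0.85) {
  if (mean_coverage <= 0) config_error("`mean_coverage` must be > 0")
  ord <- order(manifest$chrom, manifest$pos)
  manifest <- manifest[ord, , drop = FALSE]
  inside <- cpgs_in_regions(manifest, planted_lmrs)
  p_true <- ifelse(inside, lmr_level, background_level)
  with_seed(seed, {
    total <- stats::rpois(nrow(manifest), mean_coverage)
    keep <- total > 0L
    meth <- stats::rbinom(sum(keep), total[keep], p_true[keep])
    wgbs_methylome(manifest$chrom[keep], manifest$pos[keep], meth,
                   total[keep])
  })
}

#' Simulate a TPM-like expression matrix
#'
#' Effect genes get a latent Gaussian component correlated with
#' progression at `effect_r` (signs alternate so both directions occur);
#' background genes are independent. Latent values map to non-negative
#' TPM through a log-normal transform.
#'
#' @param progression Per-subject progression (years); names become sample
#'   ids.
#' @param n_genes Total genes.
#' @param n_effect_genes Number of progression-linked genes (<= `n_genes`).
#' @param effect_r Latent-scale target correlation, in \[0, 1).
#' @param seed Integer seed.
#' @param gene_ids Optional gene symbols (length `n_genes`).
#' @return Genes x subjects matrix with attribute `effect_genes`.
#' @export
simulate_expression <- function(progression, n_genes, n_effect_genes,
                                effect_r, seed = 1L, gene_ids = NULL) {
  if (effect_r < 0 || effect_r >= 1) {
    config_error("`effect_r` must be in [0, 1)")
  }
  if (n_effect_genes > n_genes) {
    config_error("`n_effect_genes` must be <= `n_genes`")
  }
  n <- length(progression)
  gene_ids <- gene_ids %||% sprintf("GENE%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) {
    config_error("`gene_ids` must have length `n_genes`")
  }
  z <- as.numeric(scale(progression))
  with_seed(seed, {
    latent <- matrix(stats::rnorm(n_genes * n), nrow = n_genes)
    effect_idx <- if (n_effect_genes > 0L) {
      sample(seq_len(n_genes), n_effect_genes)
    } else integer(0)
    signs <- rep_len(c(1, -1), n_effect_genes)
    for (i in seq_along(effect_idx)) {
      g <- effect_idx[i]
      latent[g, ] <- signs[i] * effect_r * z +
        sqrt(1 - effect_r^2) * latent[g, ]
    }
    tpm <- exp(log(50) + 0.5 * latent)
    rownames(tpm) <- gene_ids
    colnames(tpm) <- names(progression) %||% sprintf("S%04d", seq_len(n))
    attr(tpm, "effect_genes") <- gene_ids[effect_idx]
    tpm
  })
}
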