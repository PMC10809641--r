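test_that("simulate_cohort is deterministic and conserves the truth identity", {
  cfg <- sim_config(n_subjects = 40, n_cpgs = 300, n_lmrs = 10,
                    n_signal_features = 20, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$truth$true_visual_age - a$truth$chronological_age,
                   a$truth$true_progression)
})

test_that("no signal and no noise gives constant features", {
  co <- simulate_cohort(sim_config(n_subjects = 20, n_cpgs = 200,
                                   n_lmrs = 8, n_signal_features = 10,
                                   effect_size = 0, beta_noise_sd = 0,
                                   seed = 3))
  expect_equal(apply(co$beta, 1, function(r) max(r) - min(r)),
               setNames(rep(0, nrow(co$beta)), rownames(co$beta)))
})

test_that("planted LMRs respect count, span, and baseline contrast", {
  cfg <- sim_config(n_subjects = 25, n_cpgs = 500, n_lmrs = 5,
                    lmr_cpg_range = c(5, 10), n_signal_features = 10,
                    seed = 9)
  co <- simulate_cohort(cfg)
  planted <- co$truth$planted_lmr_regions
  expect_equal(nrow(planted), 5)
  expect_true(all(planted$n_cpgs >= 5 & planted$n_cpgs <= 10))
  inside <- skinclock:::cpgs_in_regions(co$manifest, planted)
  expect_equal(sum(inside), sum(planted$n_cpgs))
  expect_lt(mean(rowMeans(co$beta)[inside]), 0.3)
  expect_gt(mean(rowMeans(co$beta)[!inside]), 0.6)
  # manifest maps every CpG to a chromosome, position, and 0-2 genes
  expect_equal(nrow(co$manifest), 500)
  n_genes <- lengths(strsplit(co$manifest$gene, ","))
  expect_true(all(n_genes <= 2))
})

test_that("signal features are exactly planted and affine without noise", {
  cfg <- sim_config(n_subjects = 50, n_cpgs = 300, n_lmrs = 10,
                    n_signal_features = 25, effect_size = 0.002,
                    beta_noise_sd = 0, seed = 5)
  co <- simulate_cohort(cfg)
  sig <- co$truth$signal_feature_ids
  expect_length(sig, 25)
  prog <- co$truth$true_progression
  for (id in sig[1:5]) {
    expect_equal(abs(cor(co$beta[id, ], prog)), 1, tolerance = 1e-10)
  }
  bg <- setdiff(rownames(co$beta), sig)
  expect_true(all(apply(co$beta[bg, ], 1, function(r) max(r) - min(r)) == 0))
})

test_that("signal features correlate with progression above background", {
  co <- simulate_cohort(sim_config(n_subjects = 300, n_cpgs = 800,
                                   n_lmrs = 30, n_signal_features = 50,
                                   effect_size = 0.005, seed = 77))
  prog <- co$truth$true_progression
  r_all <- abs(as.numeric(cor(t(co$beta), prog)))
  names(r_all) <- rownames(co$beta)
  sig <- co$truth$signal_feature_ids
  expect_gt(mean(r_all[sig]), mean(r_all[setdiff(names(r_all), sig)]))
})

test_that("panel ratings reproduce the rater-noise model", {
  truth <- seq(20, 80, length.out = 11)
  exact <- simulate_panel_ratings(truth, rater_count = 5, rater_sd = 0,
                                  seed = 1)
  expect_equal(exact$mean, truth, ignore_attr = TRUE)
  expect_equal(exact$sd, rep(0, 11), ignore_attr = TRUE)
  expect_error(simulate_panel_ratings(truth, rater_count = 0, rater_sd = 1),
               class = "skinclock_config_error")
  # Monte-Carlo: median per-subject SD near the configured 11.85
  big <- simulate_panel_ratings(runif(500, 20, 80), rater_count = 30,
                                rater_sd = 11.85, seed = 4)
  expect_lt(abs(median(big$sd) - 11.85) / 11.85, 0.15)
})

test_that("wrinkle-scale ratings are clipped to [1, 100]", {
  r <- simulate_panel_ratings(rep(99, 50), rater_count = 30, rater_sd = 10,
                              seed = 2, scale = "wrinkle")
  expect_true(all(r$ratings >= 1 & r$ratings <= 100))
})

test_that("simulate_wgbs matches the count model", {
  co <- tiny_cohort(seed = 13, n_cpgs = 600)
  w <- simulate_wgbs(co$truth$planted_lmr_regions, co$manifest,
                     mean_coverage = 14, seed = 8)
  expect_true(all(w$total_count >= 1))
  expect_true(all(w$meth_count <= w$total_count))
  # fully methylated genome: binomial with p = 1
  w1 <- simulate_wgbs(co$truth$planted_lmr_regions, co$manifest,
                      mean_coverage = 14, seed = 8, lmr_level = 1,
                      background_level = 1)
  expect_identical(w1$meth_count, w1$total_count)
  # empirical coverage within 5% of the mean at 10,000 CpGs
  co2 <- simulate_cohort(sim_config(n_subjects = 5, n_cpgs = 10000,
                                    n_lmrs = 20, n_signal_features = 10,
                                    seed = 21))
  w2 <- simulate_wgbs(co2$truth$planted_lmr_regions, co2$manifest,
                      mean_coverage = 14, seed = 9)
  # correct for the omitted zero-coverage CpGs when comparing to 14
  expect_lt(abs(sum(w2$total_count) / 10000 - 14) / 14, 0.05)
})

test_that("simulate_expression plants signed correlation signal", {
  set.seed(1)
  prog <- rnorm(300, 0, 5)
  names(prog) <- sprintf("S%04d", 1:300)
  tpm <- simulate_expression(prog, n_genes = 200, n_effect_genes = 20,
                             effect_r = 0.6, seed = 6)
  expect_true(all(tpm >= 0))
  eff <- attr(tpm, "effect_genes")
  r <- abs(as.numeric(cor(t(tpm), prog)))
  names(r) <- rownames(tpm)
  expect_gt(mean(r[eff]), mean(r[setdiff(rownames(tpm), eff)]))
  expect_error(simulate_expression(prog, 10, 20, 0.5),
               class = "skinclock_config_error")
  expect_error(simulate_expression(prog, 10, 2, 1),
               class = "skinclock_config_error")
})

test_that("null expression passes the correlation filter at the nominal rate", {
  set.seed(2)
  prog <- rnorm(100, 0, 5)
  names(prog) <- sprintf("S%04d", 1:100)
  tpm <- simulate_expression(prog, n_genes = 1000, n_effect_genes = 0,
                             effect_r = 0, seed = 10)
  ct <- skinclock:::rowwise_pearson(tpm, prog)
  expect_lt(abs(mean(ct$p <= 0.05) - 0.05), 0.02)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_subjects = 0), class = "skinclock_config_error")
  expect_error(sim_config(age_range = c(50, 40)),
               class = "skinclock_config_error")
  expect_error(sim_config(rater_sd_wrinkle = -1),
               class = "skinclock_config_error")
  expect_error(sim_config(lmr_cpg_range = c(5, 3)),
               class = "skinclock_config_error")
  expect_error(sim_config(n_lmrs = 2, lmr_cpg_range = c(2, 3),
                          n_signal_features = 100),
               class = "skinclock_config_error")
})
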