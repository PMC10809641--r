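test_that("coefficient ranking sums per gene and drops unannotated features", {
  manifest <- data.frame(cpg_id = c("cg1", "cg2", "cg3", "cg4"),
                         chrom = "chr1", pos = c(10, 20, 30, 40),
                         gene = c("geneA", "geneA", "geneB", ""),
                         stringsAsFactors = FALSE)
  m <- manual_clock(c("cg1", "cg2", "cg3", "cg4"),
                    coef = c(0.5, 0.3, -0.2, 9),
                    means = rep(0.5, 4), sds = rep(1, 4), intercept = 0)
  rk <- rank_from_coefficients(m, manifest)
  expect_equal(rk$gene, c("geneA", "geneB"))
  expect_equal(rk$weight, c(0.8, -0.2))
  expect_equal(attr(rk, "n_unannotated"), 1)
})

test_that("a CpG annotated to two genes contributes to both sums", {
  manifest <- data.frame(cpg_id = c("cg1", "cg2"), chrom = "chr1",
                         pos = c(10, 20),
                         gene = c("geneA,geneB", "geneB"),
                         stringsAsFactors = FALSE)
  m <- manual_clock(c("cg1", "cg2"), coef = c(0.4, 0.1),
                    means = c(0.5, 0.5), sds = c(1, 1), intercept = 0)
  rk <- rank_from_coefficients(m, manifest)
  expect_equal(rk$weight[rk$gene == "geneA"], 0.4)
  expect_equal(rk$weight[rk$gene == "geneB"], 0.5)
})

test_that("LMR-level coefficient ranking unions member-CpG genes", {
  manifest <- data.frame(cpg_id = c("cg1", "cg2", "cg3"), chrom = "chr1",
                         pos = c(100, 110, 500),
                         gene = c("geneA", "geneA,geneB", "geneC"),
                         stringsAsFactors = FALSE)
  m <- manual_clock("chr1:95-115", coef = 0.6, means = 0.2, sds = 1,
                    intercept = 0, level = "lmr")
  rk <- rank_from_coefficients(m, manifest)
  # geneA appears in two member CpGs but the feature contributes once
  expect_equal(rk$weight[rk$gene == "geneA"], 0.6)
  expect_equal(rk$weight[rk$gene == "geneB"], 0.6)
  expect_false("geneC" %in% rk$gene)
})

test_that("methylation ranking filters by p and averages per gene", {
  set.seed(113)
  preds <- rnorm(30)
  names(preds) <- sprintf("S%02d", 1:30)
  # two correlated CpGs for geneA, one anti-correlated for geneB, noise cg
  b <- rbind(cg1 = 0.5 + 0.02 * preds + rnorm(30, 0, 0.005),
             cg2 = 0.5 + 0.01 * preds + rnorm(30, 0, 0.005),
             cg3 = 0.5 - 0.02 * preds + rnorm(30, 0, 0.005),
             cg4 = runif(30, 0.4, 0.6))
  colnames(b) <- names(preds)
  b <- beta_matrix(b, "cpg")
  manifest <- data.frame(cpg_id = rownames(b), chrom = "chr1",
                         pos = c(10, 20, 30, 40),
                         gene = c("geneA", "geneA", "geneB", "geneC"),
                         stringsAsFactors = FALSE)
  rk <- rank_from_methylation_correlation(b, preds, manifest)
  ct <- skinclock:::rowwise_pearson(unclass(b), preds)
  expect_equal(rk$weight[rk$gene == "geneA"],
               mean(ct$r[1:2]), tolerance = 1e-12)
  expect_equal(rk$weight[rk$gene == "geneB"], unname(ct$r[3]),
               tolerance = 1e-12)
  expect_false("geneC" %in% rk$gene)  # p = 0.2-ish, discarded
  expect_gt(ct$p[4], 0.05)
})

test_that("expression ranking averages duplicate genes after filtering", {
  set.seed(127)
  preds <- rnorm(40)
  names(preds) <- sprintf("S%02d", 1:40)
  tpm <- rbind(5 + 2 * preds + rnorm(40, 0, 0.3),
               5 + 1 * preds + rnorm(40, 0, 0.3),
               10 - 3 * preds + rnorm(40, 0, 0.3),
               runif(40, 4, 6))
  rownames(tpm) <- c("geneA", "geneA", "geneB", "geneC")
  colnames(tpm) <- names(preds)
  rk <- rank_from_expression_correlation(tpm, preds)
  ct <- skinclock:::rowwise_pearson(tpm, preds)
  expect_equal(rk$weight[rk$gene == "geneA"], mean(ct$r[1:2]),
               tolerance = 1e-12)
  # anti-correlated gene sits at the bottom with negative weight
  expect_equal(rk$gene[nrow(rk)], "geneB")
  expect_lt(rk$weight[nrow(rk)], 0)
})

test_that("null methylation survives the p filter at the nominal rate", {
  set.seed(131)
  preds <- rnorm(60)
  names(preds) <- sprintf("S%02d", 1:60)
  b <- matrix(runif(2000 * 60, 0.3, 0.7), nrow = 2000,
              dimnames = list(sprintf("cg%04d", 1:2000), names(preds)))
  ct <- skinclock:::rowwise_pearson(b, preds)
  expect_lt(abs(mean(ct$p <= 0.05) - 0.05), 0.02)
})

test_that("enrichment score handles the extreme single-gene sets", {
  rk <- toy_ranking(10)
  top <- enrichment_score(rk, rk$gene[1])
  expect_equal(top$es, 1.0)
  bottom <- enrichment_score(rk, rk$gene[10])
  expect_equal(bottom$es, -1.0)
  expect_error(enrichment_score(rk, "absent"),
               class = "skinclock_empty_overlap_error")
  expect_error(enrichment_score(rk, rk$gene),
               class = "skinclock_degenerate_set_error")
})

test_that("the five-gene worked example matches the brute-force oracle", {
  rk <- ranked_gene_list(paste0("g", 1:5), c(3, 2, 1, 1, 1))
  got <- enrichment_score(rk, c("g1", "g3"))
  expect_equal(got$es, oracle_es(rk, c("g1", "g3")))
  expect_equal(got$hit_indices, c(1L, 3L))
})

test_that("streaming ES equals the all-prefix oracle on random instances", {
  set.seed(137)
  for (i in 1:25) {
    N <- sample(5:50, 1)
    rk <- ranked_gene_list(sprintf("g%03d", 1:N),
                           sort(rnorm(N), decreasing = TRUE))
    set_size <- sample(seq_len(N - 1), 1)
    gs <- sample(rk$gene, set_size)
    expect_equal(enrichment_score(rk, gs)$es, oracle_es(rk, gs),
                 tolerance = 1e-12)
  }
})

test_that("the positions-only ES fast path agrees with the streaming scan", {
  set.seed(139)
  for (i in 1:25) {
    N <- sample(10:80, 1)
    w <- abs(rnorm(N))
    rk <- ranked_gene_list(sprintf("g%03d", 1:N),
                           sort(rnorm(N), decreasing = TRUE))
    idx <- sample(N, sample(seq_len(N - 1), 1))
    expect_equal(skinclock:::es_from_positions(abs(rk$weight), idx, N),
                 enrichment_score(rk, rk$gene[idx])$es,
                 tolerance = 1e-12)
  }
})

test_that("ES is invariant to positive rescaling of weights", {
  rk <- toy_ranking(20, seed = 5)
  gs <- rk$gene[c(2, 5, 11)]
  rk2 <- ranked_gene_list(rk$gene, rk$weight * 37.5)
  expect_equal(enrichment_score(rk2, gs)$es, enrichment_score(rk, gs)$es,
               tolerance = 1e-12)
})

test_that("permutation null is seeded, bounded, and finds planted sets", {
  rk <- ranked_gene_list(sprintf("g%02d", 1:50),
                         seq(5, 0.1, length.out = 50))
  gs <- rk$gene[1:5]
  a <- permutation_null(rk, gs, n_perm = 1000, seed = 7)
  b <- permutation_null(rk, gs, n_perm = 1000, seed = 7)
  expect_identical(a, b)
  expect_gte(a$p_value, 1 / 1001)
  expect_lte(a$p_value, 0.01)
  expect_gt(a$nes, 1)
})

test_that("nominal p is approximately uniform under the null", {
  set.seed(149)
  ps <- replicate(200, {
    N <- 100
    rk <- ranked_gene_list(sprintf("g%03d", 1:N),
                           sort(rnorm(N), decreasing = TRUE))
    gs <- sample(rk$gene, 10)
    permutation_null(rk, gs, n_perm = 99,
                     seed = sample.int(10^6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("run_preranked truncates to top_k by |NES| and is deterministic", {
  set.seed(151)
  N <- 120
  rk <- ranked_gene_list(sprintf("g%03d", 1:N),
                         sort(rnorm(N), decreasing = TRUE))
  small <- lapply(1:3, function(i) sample(rk$gene, 8))
  names(small) <- paste0("set", 1:3)
  res3 <- run_preranked(list(src = rk), small, n_perm = 50, seed = 1)
  expect_lte(nrow(res3$top$src), 3)
  many <- lapply(1:30, function(i) sample(rk$gene, 8))
  names(many) <- sprintf("set%02d", 1:30)
  res30 <- run_preranked(list(src = rk), many, n_perm = 50, seed = 1)
  expect_equal(nrow(res30$top$src), 20)
  expect_equal(nrow(res30$full$src), 30)
  # identical ranking provided twice gives identical tables
  twin <- run_preranked(list(a = rk, b = rk), many, n_perm = 50, seed = 1)
  expect_equal(twin$top$a$nes, twin$top$b$nes)
})

test_that("sets with no ranked genes are skipped with a warning", {
  rk <- toy_ranking(10)
  sets <- list(ok = rk$gene[1:3], gone = c("zz1", "zz2"))
  expect_warning(res <- run_preranked(list(src = rk), sets, n_perm = 20,
                                      seed = 1),
                 "no overlap")
  expect_equal(res$full$src$set, "ok")
})

test_that("consensus keeps the overlap structure and sorts by mean |NES|", {
  mk <- function(sets, nes) data.frame(set = sets, nes = nes,
                                       size = 10, stringsAsFactors = FALSE)
  srcs <- lapply(1:7, function(i) {
    sets <- c("X", if (i <= 6) "Y", if (i <= 5) "Z")
    mk(sets, seq(2, by = -0.1, length.out = length(sets)))
  })
  out <- consensus(srcs, min_sources = 6)
  expect_setequal(out$pathway, c("X", "Y"))
  expect_equal(out$n_sources[out$pathway == "X"], 7L)
  expect_equal(out$n_sources[out$pathway == "Y"], 6L)
  expect_true(all(diff(out$mean_abs_nes) <= 0))
  # disjoint sources yield an empty table
  dis <- lapply(1:3, function(i) mk(paste0("only", i), 1.5))
  expect_equal(nrow(consensus(dis, min_sources = 2)), 0)
  # single source: re-sorted copy of its own top list
  one <- consensus(list(mk(c("a", "b"), c(-2.5, 1.0))), min_sources = 1)
  expect_equal(one$pathway, c("a", "b"))
  expect_equal(one$mean_abs_nes, c(2.5, 1.0))
})

test_that("GMT and RNK files round-trip", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g2", "g9"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_equal(read_gmt(gmt), sets)
  rk <- toy_ranking(8)
  rnk <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rk, rnk)
  back <- read_rnk(rnk)
  expect_equal(back$gene, rk$gene)
  expect_equal(back$weight, rk$weight, tolerance = 1e-12)
})
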