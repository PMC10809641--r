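flat_methylome <- function(levels, coverage = 10, gap = 50,
                           chrom = "chr1") {
  n <- length(levels)
  wgbs_methylome(rep(chrom, n), seq(0, by = gap, length.out = n),
                 round(levels * coverage), rep(coverage, n))
}

test_that("smoothing pools counts over the window", {
  m <- flat_methylome(c(0.5, 0.5, 0.5), coverage = 2)
  expect_equal(smooth_methylation(m, 1), m$meth_count / m$total_count)
  expect_equal(smooth_methylation(m, 3)[2], 3 / 6)
  expect_error(smooth_methylation(m, 2), class = "skinclock_config_error")
})

test_that("smoothing equals the brute-force windowed oracle", {
  set.seed(41)
  for (window in c(1, 3, 5)) {
    total <- rpois(200, 12) + 1
    meth <- rbinom(200, total, runif(200))
    m <- wgbs_methylome(rep(c("chr1", "chr2"), each = 100),
                        rep(seq(0, by = 37, length.out = 100), 2),
                        meth, total)
    got <- smooth_methylation(m, window)
    want <- c(oracle_smooth(m$meth_count[1:100], m$total_count[1:100],
                            window),
              oracle_smooth(m$meth_count[101:200], m$total_count[101:200],
                            window))
    expect_equal(got, want)
  }
})

test_that("segmentation finds forced runs with exact coordinates", {
  lv <- c(rep(0.9, 5), rep(0.1, 10), rep(0.9, 5))
  m <- flat_methylome(lv)
  p <- seg_params(meth_cutoff = 0.5, min_cpgs = 4, smoothing_window = 1)
  seg <- segment_hypomethylated(m, p)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_cpgs, 10)
  expect_equal(seg$start, m$pos[6])
  expect_equal(seg$end, m$pos[15] + 1L)
  expect_equal(seg$mean_methylation, 0.1)
})

test_that("segmentation respects the cutoff and minimum-CpG rules", {
  all_high <- flat_methylome(rep(0.9, 30))
  expect_equal(nrow(segment_hypomethylated(all_high, seg_params())), 0)
  short_run <- flat_methylome(c(rep(0.9, 5), rep(0.1, 3), rep(0.9, 5)))
  p <- seg_params(min_cpgs = 4, smoothing_window = 1)
  expect_equal(nrow(segment_hypomethylated(short_run, p)), 0)
})

test_that("segments never overlap, are maximal, and ignore row order", {
  set.seed(43)
  for (i in 1:5) {
    lv <- runif(300)
    m <- flat_methylome(lv, coverage = 20)
    p <- seg_params(min_cpgs = 3, smoothing_window = 1)
    seg <- segment_hypomethylated(m, p)
    if (nrow(seg) > 1) {
      expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
    }
    # maximality: the CpG just before/after each segment is >= cutoff
    raw <- m$meth_count / m$total_count
    for (j in seq_len(nrow(seg))) {
      lo <- which(m$pos == seg$start[j])
      hi <- which(m$pos == seg$end[j] - 1L)
      if (lo > 1) expect_gte(raw[lo - 1], p$meth_cutoff)
      if (hi < nrow(m)) expect_gte(raw[hi + 1], p$meth_cutoff)
    }
    # processing order: shuffle input rows, constructor restores order
    perm <- sample(nrow(m))
    m2 <- wgbs_methylome(m$chrom[perm], m$pos[perm], m$meth_count[perm],
                         m$total_count[perm])
    expect_equal(segment_hypomethylated(m2, p), seg)
  }
})

test_that("LMR/UMR classification splits at the inclusive boundary", {
  reg <- region_set(rep("chr1", 3), c(0, 100, 200), c(50, 150, 250),
                    c(10, 30, 45), c(0.1, 0.1, 0.1))
  out <- classify_segments(reg, lmr_max_cpgs = 30)
  expect_equal(out$class, c("LMR", "LMR", "UMR"))
})

test_that("wgbs_methylome enforces its invariants", {
  expect_error(wgbs_methylome("chr1", c(1, 1), c(0, 0), c(1, 1)),
               class = "skinclock_data_error")
  expect_error(wgbs_methylome("chr1", 1, 2, 1),
               class = "skinclock_data_error")
  expect_error(wgbs_methylome("chr1", 1, 0, 0),
               class = "skinclock_data_error")
})

test_that("an i.i.d.-shuffled methylome yields FDR near 1 and no selection", {
  set.seed(47)
  # marginal mixture like real data, but no spatial structure at all
  lv <- sample(c(runif(60, 0.05, 0.25), runif(240, 0.65, 0.95)))
  m <- flat_methylome(lv, coverage = 14)
  p <- seg_params(n_shuffles = 10, seed = 7)
  expect_error(calibrate_fdr(m, p), class = "skinclock_calibration_error")
  # the table (attached to the condition) shows high FDR where segments occur
  tab <- tryCatch(calibrate_fdr(m, p),
                  skinclock_calibration_error = function(e) e$fdr_table)
  busy <- tab[!is.na(tab$fdr) & tab$observed >= 5, ]
  expect_true(all(busy$fdr >= 0.5))
})

test_that("calibration recovers strongly planted regions", {
  set.seed(53)
  # 20 planted 6-10 CpG regions in a 4000-CpG background
  n <- 4000
  lv <- runif(n, 0.75, 0.95)
  starts <- seq(100, by = 190, length.out = 20)
  lens <- sample(6:10, 20, replace = TRUE)
  for (i in seq_along(starts)) {
    lv[starts[i]:(starts[i] + lens[i] - 1)] <- runif(lens[i], 0.05, 0.2)
  }
  total <- rpois(n, 14) + 1L
  m <- wgbs_methylome(rep("chr1", n), seq(0, by = 60, length.out = n),
                      rbinom(n, total, lv), total)
  p <- seg_params(n_shuffles = 5, seed = 3)
  cal <- calibrate_fdr(m, p)
  p$meth_cutoff <- cal$meth_cutoff
  p$min_cpgs <- cal$min_cpgs
  seg <- segment_hypomethylated(m, p)
  truth <- region_set(rep("chr1", 20), (starts - 1) * 60,
                      (starts + lens - 2) * 60 + 1, lens, 0.1, "LMR")
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(truth$start + 1, truth$end)),
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(seg$start + 1, seg$end)))
  expect_gte(length(unique(S4Vectors::queryHits(ov))) / 20, 0.95)
})

test_that("probe intersection keeps covered LMRs only", {
  co <- tiny_cohort(seed = 29, n_cpgs = 300, n_lmrs = 8, n_signal = 10)
  planted <- co$truth$planted_lmr_regions
  # add an uncovered LMR and a heavily covered UMR
  extra <- region_set(c("chr1", "chr1"),
                      c(10^7, co$manifest$pos[co$manifest$chrom == "chr1"][1]),
                      c(10^7 + 100,
                        max(co$manifest$pos[co$manifest$chrom == "chr1"]) + 1),
                      c(5, 40), c(0.1, 0.2), c("LMR", "UMR"))
  all_reg <- rbind(planted, extra)
  out <- intersect_with_probes(all_reg, co$manifest)
  expect_equal(nrow(out), nrow(planted))
  expect_true(all(out$class == "LMR"))
  expect_equal(attr(out, "n_dropped"), 1)
  # chromosome mismatch is a data error naming the chromosome
  bad <- region_set("chrX", 0, 10, 4, 0.1, "LMR")
  expect_error(intersect_with_probes(bad, co$manifest), "chrX",
               class = "skinclock_data_error")
})
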