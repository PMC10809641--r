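# Low-methylated-region (LMR) calling from WGBS-like counts.
#
# Cutoff-based segmentation of smoothed methylation with FDR-calibrated
# selection of the methylation cutoff m and minimum CpG count n, followed
# by the LMR/UMR split at a CpG-count threshold and intersection with
# array probes.

#' Construct a region set
#'
#' Genomic intervals in 0-based half-open coordinates with CpG counts,
#' pooled mean methylation, and an LMR/UMR class label.
#'
#' @param chrom,start,end,n_cpgs,mean_methylation,class Per-region vectors.
#' @return A `region_set` data.frame.
#' @export
region_set <- function(chrom = character(0), start = integer(0),
                       end = integer(0), n_cpgs = integer(0),
                       mean_methylation = numeric(0),
                       class = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), n_cpgs = as.integer(n_cpgs),
                   mean_methylation = as.numeric(mean_methylation),
                   class = rep_len(as.character(class),
                                   length.out = length(chrom)),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L && any(df$start >= df$end)) {
    data_error("region start must be < end (0-based half-open)")
  }
  rownames(df) <- NULL
  structure(df, class = c("region_set", "data.frame"))
}

#' Construct a WGBS methylome
#'
#' Ordered per-CpG (position, methylated count, total count) records per
#' chromosome; positions 0-based and strictly increasing within
#' chromosome, total counts >= 1.
#'
#' @param chrom,pos,meth_count,total_count Per-CpG vectors.
#' @return A `wgbs_methylome` data.frame sorted by (chrom, pos).
#' @export
wgbs_methylome <- function(chrom, pos, meth_count, total_count) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   meth_count = as.integer(meth_count),
                   total_count = as.integer(total_count),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$total_count < 1L)) {
    data_error("retained CpGs must have total count >= 1")
  }
  if (any(df$meth_count < 0L | df$meth_count > df$total_count)) {
    data_error("need 0 <= meth_count <= total_count")
  }
  dup <- unlist(tapply(df$pos, df$chrom, function(p) duplicated(p)),
                use.names = FALSE)
  if (any(dup)) data_error("CpG positions must be unique per chromosome")
  structure(df, class = c("wgbs_methylome", "data.frame"))
}

#' Segmentation parameters
#'
#' @param meth_cutoff Methylation cutoff m in (0, 1); CpGs below it are
#'   candidate members (default 0.5).
#' @param min_cpgs Minimum CpGs per segment n (default 4).
#' @param smoothing_window Odd CpG-count smoothing window (default 3).
#' @param lmr_max_cpgs LMR/UMR split: segments with up to this many CpGs
#'   are LMRs (default 30, inclusive).
#' @param fdr_target Target FDR for cutoff calibration (default 0.05).
#' @param n_shuffles Number of within-chromosome permutations for the FDR
#'   null (default 10).
#' @param seed Integer seed for the permutations.
#' @return A validated `seg_params` list.
#' @export
seg_params <- function(meth_cutoff = 0.5, min_cpgs = 4L,
                       smoothing_window = 3L, lmr_max_cpgs = 30L,
                       fdr_target = 0.05, n_shuffles = 10L, seed = 1L) {
  p <- list(meth_cutoff = meth_cutoff, min_cpgs = as.integer(min_cpgs),
            smoothing_window = as.integer(smoothing_window),
            lmr_max_cpgs = as.integer(lmr_max_cpgs),
            fdr_target = fdr_target, n_shuffles = as.integer(n_shuffles),
            seed = as.integer(seed))
  if (p$meth_cutoff <= 0 || p$meth_cutoff >= 1) {
    config_error("`meth_cutoff` must be in (0, 1)")
  }
  if (p$min_cpgs < 1L) config_error("`min_cpgs` must be >= 1")
  if (p$smoothing_window < 1L || p$smoothing_window %% 2L == 0L) {
    config_error("`smoothing_window` must be odd and >= 1")
  }
  if (p$fdr_target <= 0 || p$fdr_target >= 1) {
    config_error("`fdr_target` must be in (0, 1)")
  }
  class(p) <- "seg_params"
  p
}

#' Smooth per-CpG methylation by pooled counts
#'
#' The smoothed level at CpG i is (sum meth) / (sum total) over the window
#' of CpGs centred at i, truncated at chromosome ends.
#'
#' @param methylome A [wgbs_methylome()].
#' @param window Odd window size in CpGs (1 = raw fraction).
#' @return Numeric vector aligned with the methylome rows, in \[0, 1\].
#' @export
smooth_methylation <- function(methylome, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    config_error("`window` must be odd and >= 1")
  }
  h <- (window - 1L) %/% 2L
  out <- numeric(nrow(methylome))
  for (ch in unique(methylome$chrom)) {
    idx <- which(methylome$chrom == ch)
    nc <- length(idx)
    cm <- c(0, cumsum(methylome$meth_count[idx]))
    ct <- c(0, cumsum(methylome$total_count[idx]))
    lo <- pmax(seq_len(nc) - h, 1L)
    hi <- pmin(seq_len(nc) + h, nc)
    out[idx] <- (cm[hi + 1L] - cm[lo]) / (ct[hi + 1L] - ct[lo])
  }
  out
}

#' Segment hypomethylated runs
#'
#' Finds maximal runs of consecutive CpGs whose smoothed methylation is
#' below `meth_cutoff`, keeping runs of at least `min_cpgs` CpGs. A
#' region spans first CpG position to last CpG position + 1 (half-open);
#' its mean methylation is the pooled meth/total over member CpGs.
#'
#' @param methylome A [wgbs_methylome()].
#' @param params A [seg_params()].
#' @return An unclassified [region_set()].
#' @export
segment_hypomethylated <- function(methylome, params = seg_params()) {
  sm <- smooth_methylation(methylome, params$smoothing_window)
  pieces <- lapply(unique(methylome$chrom), function(ch) {
    idx <- which(methylome$chrom == ch)
    below <- sm[idx] < params$meth_cutoff
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= params$min_cpgs)
    if (length(keep) == 0L) return(NULL)
    do.call(rbind, lapply(keep, function(k) {
      mem <- idx[starts[k]:ends[k]]
      data.frame(chrom = ch,
                 start = methylome$pos[mem[1]],
                 end = methylome$pos[mem[length(mem)]] + 1L,
                 n_cpgs = length(mem),
                 mean_methylation = sum(methylome$meth_count[mem]) /
                   sum(methylome$total_count[mem]),
                 stringsAsFactors = FALSE)
    }))
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces)) return(region_set())
  region_set(pieces$chrom, pieces$start, pieces$end, pieces$n_cpgs,
             pieces$mean_methylation)
}

#' Classify segments as LMR or UMR
#'
#' Segments with `n_cpgs <= lmr_max_cpgs` become LMRs (the boundary is
#' inclusive); larger segments become UMRs.
#'
#' @param regions A [region_set()].
#' @param lmr_max_cpgs CpG-count split point (default 30).
#' @return The region set with `class` filled in.
#' @export
classify_segments <- function(regions, lmr_max_cpgs = 30L) {
  regions$class <- ifelse(regions$n_cpgs <= lmr_max_cpgs, "LMR", "UMR")
  regions
}

count_segments <- function(methylome, m, n, window) {
  sm <- smooth_methylation(methylome, window)
  total <- 0L
  for (ch in unique(methylome$chrom)) {
    below <- sm[methylome$chrom == ch] < m
    r <- rle(below)
    total <- total + sum(r$values & r$lengths >= n)
  }
  total
}

shuffle_methylome <- function(methylome) {
  for (ch in unique(methylome$chrom)) {
    idx <- which(methylome$chrom == ch)
    perm <- sample(length(idx))
    methylome$meth_count[idx] <- methylome$meth_count[idx][perm]
    methylome$total_count[idx] <- methylome$total_count[idx][perm]
  }
  methylome
}

#' FDR-calibrated selection of segmentation cutoffs
#'
#' For each (m, n) on a grid, the FDR estimate is the mean segment count
#' over methylomes with (meth, total) pairs permuted within chromosome,
#' divided by the observed segment count (capped at 1). The least
#' stringent grid point meeting `fdr_target` is selected: the largest m,
#' with ties broken towards the smallest n.
#'
#' @param methylome A [wgbs_methylome()].
#' @param params A [seg_params()]; `n_shuffles` and `seed` drive the null.
#' @param m_grid,n_grid Candidate cutoffs.
#' @return List with `meth_cutoff`, `min_cpgs`, and `fdr_table`
#'   (m, n, observed, null mean, FDR estimate).
#' @export
calibrate_fdr <- function(methylome, params = seg_params(),
                          m_grid = seq(0.3, 0.7, by = 0.1),
                          n_grid = 3:6) {
  if (params$n_shuffles < 1L) config_error("`n_shuffles` must be >= 1")
  grid <- expand.grid(m = m_grid, n = n_grid)
  observed <- mapply(function(m, n) {
    count_segments(methylome, m, n, params$smoothing_window)
  }, grid$m, grid$n)
  if (all(observed == 0L)) {
    skinclock_error("no segments observed at any grid point",
                    "skinclock_calibration_error")
  }
  null_counts <- with_seed(params$seed, {
    vapply(seq_len(params$n_shuffles), function(s) {
      shuffled <- shuffle_methylome(methylome)
      mapply(function(m, n) {
        count_segments(shuffled, m, n, params$smoothing_window)
      }, grid$m, grid$n)
    }, numeric(nrow(grid)))
  })
  null_mean <- rowMeans(matrix(null_counts, nrow = nrow(grid)))
  fdr <- ifelse(observed > 0, pmin(1, null_mean / observed), NA_real_)
  tab <- data.frame(m = grid$m, n = grid$n, observed = observed,
                    null_mean = null_mean, fdr = fdr)
  ord <- order(-tab$m, tab$n)
  pass <- ord[!is.na(tab$fdr[ord]) & tab$fdr[ord] <= params$fdr_target]
  if (length(pass) == 0L) {
    skinclock_error("no grid point achieves the FDR target",
                    "skinclock_calibration_error", fdr_table = tab)
  }
  sel <- pass[1L]
  list(meth_cutoff = tab$m[sel], min_cpgs = tab$n[sel], fdr_table = tab)
}

# Logical flag per manifest CpG: does it fall inside any region?
cpgs_in_regions <- function(manifest, regions) {
  if (nrow(regions) == 0L) return(rep(FALSE, nrow(manifest)))
  gr_pos <- GenomicRanges::GRanges(
    manifest$chrom, IRanges::IRanges(manifest$pos + 1L, width = 1L))
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  IRanges::overlapsAny(gr_pos, gr_reg)
}

#' Intersect LMRs with array probes
#'
#' Keeps only regions classified as LMR that contain at least one manifest
#' CpG; UMRs are excluded. The number of LMRs dropped for lacking probes
#' is attached as attribute `n_dropped`.
#'
#' @param regions Classified [region_set()].
#' @param manifest CpG manifest (0-based `pos`).
#' @return Subset region set of probe-covered LMRs.
#' @export
intersect_with_probes <- function(regions, manifest) {
  lmrs <- regions[regions$class %in% "LMR", , drop = FALSE]
  missing_chrom <- setdiff(unique(lmrs$chrom), unique(manifest$chrom))
  if (length(missing_chrom) > 0L) {
    data_error(sprintf(
      "region chromosomes absent from manifest: %s",
      paste(missing_chrom, collapse = ", ")))
  }
  if (nrow(lmrs) == 0L) {
    out <- lmrs
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  gr_reg <- GenomicRanges::GRanges(
    lmrs$chrom, IRanges::IRanges(lmrs$start + 1L, lmrs$end))
  gr_pos <- GenomicRanges::GRanges(
    manifest$chrom, IRanges::IRanges(manifest$pos + 1L, width = 1L))
  hits <- GenomicRanges::countOverlaps(gr_reg, gr_pos)
  out <- lmrs[hits > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(hits == 0L)
  out
}
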