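# Gene ranking, preranked gene-set enrichment (weighted
# Kolmogorov-Smirnov running sum), and the multi-source pathway
# consensus.

#' Construct a ranked gene list
#'
#' Genes are unique, weights signed and finite; rows are sorted by weight
#' descending with ties broken by gene id so the order is stable.
#'
#' @param gene Character vector of gene symbols.
#' @param weight Numeric weights.
#' @param source_tag Optional label describing the ranking's origin.
#' @return A `ranked_gene_list` data.frame (`gene`, `weight`).
#' @export
ranked_gene_list <- function(gene, weight, source_tag = NULL) {
  if (length(gene) != length(weight)) {
    data_error("gene and weight lengths differ")
  }
  if (anyDuplicated(gene)) data_error("ranked genes must be unique")
  if (any(!is.finite(weight))) data_error("ranking weights must be finite")
  ord <- order(-weight, gene)
  df <- data.frame(gene = as.character(gene)[ord],
                   weight = as.numeric(weight)[ord],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("ranked_gene_list", "data.frame"),
            source_tag = source_tag)
}

# Expand the manifest's comma-separated gene column into
# (cpg_id, gene) pairs; CpGs without annotation contribute no rows.
manifest_gene_pairs <- function(manifest) {
  genes <- strsplit(manifest$gene, ",", fixed = TRUE)
  n <- lengths(genes)
  data.frame(cpg_id = rep(manifest$cpg_id, n),
             gene = unlist(genes, use.names = FALSE),
             stringsAsFactors = FALSE)
}

parse_region_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    data_error(sprintf("feature id is not chrom:start-end (e.g. %s)",
                       ids[bad][1]))
  }
  data.frame(chrom = vapply(m, `[[`, character(1), 2L),
             start = as.integer(vapply(m, `[[`, character(1), 3L)),
             end = as.integer(vapply(m, `[[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

# Genes annotated to each model feature (a list parallel to feature_ids):
# for CpG-level features the CpG's own genes; for LMR-level features the
# union of genes of member CpGs.
feature_genes <- function(feature_ids, level, manifest) {
  pairs <- manifest_gene_pairs(manifest)
  if (level == "cpg") {
    split_genes <- split(pairs$gene, pairs$cpg_id)
    lapply(feature_ids, function(id) unique(split_genes[[id]]) %||%
             character(0))
  } else {
    reg <- parse_region_ids(feature_ids)
    gr_reg <- GenomicRanges::GRanges(
      reg$chrom, IRanges::IRanges(reg$start + 1L, reg$end))
    gr_pos <- GenomicRanges::GRanges(
      manifest$chrom, IRanges::IRanges(manifest$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr_reg, gr_pos)
    split_genes <- split(pairs$gene, pairs$cpg_id)
    lapply(seq_along(feature_ids), function(i) {
      cpgs <- manifest$cpg_id[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]
      unique(unlist(split_genes[cpgs], use.names = FALSE)) %||% character(0)
    })
  }
}

#' Rank genes by summed model coefficients
#'
#' Every model feature's coefficient is assigned to each gene annotated
#' to any of its member CpGs; the per-gene weight is the sum of assigned
#' coefficients (signed). Features with no gene annotation are dropped;
#' their count is attached as attribute `n_unannotated`.
#'
#' @param model A `clock_model` (CpG- or LMR-level).
#' @param manifest CpG manifest with gene annotation.
#' @return A [ranked_gene_list()] tagged `"coefficient"`.
#' @export
rank_from_coefficients <- function(model, manifest) {
  genes_per_feature <- feature_genes(model$feature_ids,
                                     model$feature_level, manifest)
  n_genes <- lengths(genes_per_feature)
  gene <- unlist(genes_per_feature, use.names = FALSE)
  weight <- rep(model$coefficients, n_genes)
  if (length(gene) == 0L) {
    skinclock_error("no model feature maps to a gene",
                    "skinclock_empty_ranking_error")
  }
  sums <- tapply(weight, gene, sum)
  out <- ranked_gene_list(names(sums), as.numeric(sums),
                          source_tag = "coefficient")
  attr(out, "n_unannotated") <- sum(n_genes == 0L)
  out
}

# Row-wise Pearson r and two-sided t-test p of a matrix against a vector.
# Zero-variance rows yield NA (and never survive a p filter).
rowwise_pearson <- function(m, v) {
  n <- length(v)
  vc <- v - mean(v)
  mc <- m - rowMeans(m)
  denom <- sqrt(rowSums(mc^2) * sum(vc^2))
  r <- ifelse(denom > 0, as.numeric(mc %*% vc) / denom, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  list(r = r, p = p)
}

#' Rank genes by CpG methylation-prediction correlation
#'
#' Per CpG, the Pearson correlation (and two-sided p) between its beta
#' values and the clock predictions is computed; CpGs with p above
#' `p_cut` are discarded. Surviving CpGs are annotated to genes and the
#' per-gene weight is the mean of its CpGs' correlations.
#'
#' @param beta CpG-level beta matrix.
#' @param predictions Named per-sample predictions covering the beta
#'   samples.
#' @param manifest CpG manifest with gene annotation.
#' @param p_cut Discard threshold (default 0.05).
#' @return A [ranked_gene_list()] tagged `"methylation_correlation"`.
#' @export
rank_from_methylation_correlation <- function(beta, predictions, manifest,
                                              p_cut = 0.05) {
  if (ncol(beta) < 3L) data_error("need at least 3 samples")
  preds <- predictions[colnames(beta)]
  if (anyNA(preds)) data_error("predictions missing for some beta samples")
  ct <- rowwise_pearson(beta, preds)
  keep <- !is.na(ct$p) & ct$p <= p_cut
  if (!any(keep)) {
    skinclock_error("no CpG survives the correlation p filter",
                    "skinclock_empty_ranking_error")
  }
  surv <- data.frame(cpg_id = rownames(beta)[keep], r = ct$r[keep],
                     stringsAsFactors = FALSE)
  pairs <- manifest_gene_pairs(manifest)
  merged <- merge(surv, pairs, by = "cpg_id")
  if (nrow(merged) == 0L) {
    skinclock_error("no surviving CpG maps to a gene",
                    "skinclock_empty_ranking_error")
  }
  means <- tapply(merged$r, merged$gene, mean)
  ranked_gene_list(names(means), as.numeric(means),
                   source_tag = "methylation_correlation")
}

#' Rank genes by expression-prediction correlation
#'
#' As [rank_from_methylation_correlation()], but rows are genes natively;
#' duplicate gene rows surviving the filter have their correlations
#' averaged.
#'
#' @param tpm Genes x samples expression matrix (rownames = genes).
#' @param predictions Named per-sample predictions.
#' @param p_cut Discard threshold (default 0.05).
#' @return A [ranked_gene_list()] tagged `"expression_correlation"`.
#' @export
rank_from_expression_correlation <- function(tpm, predictions,
                                             p_cut = 0.05) {
  if (ncol(tpm) < 3L) data_error("need at least 3 samples")
  preds <- predictions[colnames(tpm)]
  if (anyNA(preds)) data_error("predictions missing for some samples")
  ct <- rowwise_pearson(tpm, preds)
  keep <- !is.na(ct$p) & ct$p <= p_cut
  if (!any(keep)) {
    skinclock_error("no gene survives the correlation p filter",
                    "skinclock_empty_ranking_error")
  }
  means <- tapply(ct$r[keep], rownames(tpm)[keep], mean)
  ranked_gene_list(names(means), as.numeric(means),
                   source_tag = "expression_correlation")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking the ranking top to bottom, hits increment the running sum by
#' `|weight|^exponent / sum_set |weight|^exponent` and misses decrement it
#' by `1 / (N - set size)`. The enrichment score is the running-sum value
#' of maximal absolute deviation from zero (signed; first such position
#' on ties).
#'
#' @param ranking A [ranked_gene_list()].
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Weighting exponent (default 1).
#' @return List with `es`, `running_sum`, `hit_indices`.
#' @export
enrichment_score <- function(ranking, gene_set, weight_exponent = 1) {
  hit <- ranking$gene %in% gene_set
  N <- nrow(ranking)
  nh <- sum(hit)
  if (nh == 0L) {
    skinclock_error("gene set has no overlap with the ranking",
                    "skinclock_empty_overlap_error")
  }
  if (nh == N) {
    skinclock_error("gene set covers the entire ranking",
                    "skinclock_degenerate_set_error")
  }
  w <- abs(ranking$weight)^weight_exponent
  denom <- sum(w[hit])
  step <- numeric(N)
  if (denom > 0) {
    step[hit] <- w[hit] / denom
  } else {
    step[hit] <- 1 / nh  # all-zero weights: fall back to equal hit mass
  }
  step[!hit] <- -1 / (N - nh)
  run <- cumsum(step)
  i <- which.max(abs(run))
  list(es = run[i], running_sum = run, hit_indices = which(hit))
}

# ES from hit positions only (O(k log k)); used for permutation nulls.
# Extrema of the running sum occur immediately after a hit or immediately
# before the next hit, which this enumerates exactly.
es_from_positions <- function(w_abs, idx, N) {
  k <- length(idx)
  idx <- sort.int(idx)
  wh <- w_abs[idx]
  denom <- sum(wh)
  inc <- if (denom > 0) wh / denom else rep(1 / k, k)
  dm <- 1 / (N - k)
  H <- cumsum(inc)
  after <- H - (idx - seq_len(k)) * dm
  before <- c(0, H[-k]) - (idx - 1L - (seq_len(k) - 1L)) * dm
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Permutation null, NES, and nominal p for one gene set
#'
#' Null enrichment scores come from random gene sets of the same size
#' drawn from the ranking's genes. NES divides the observed ES by the
#' mean |null ES| restricted to null values sharing the observed sign;
#' the nominal p uses the plus-one estimator on the same-signed null.
#'
#' @param ranking A [ranked_gene_list()].
#' @param gene_set Character vector of member genes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param weight_exponent Weighting exponent (default 1).
#' @return List with `es`, `nes`, `p_value`, `size`, `n_perm`.
#' @export
permutation_null <- function(ranking, gene_set, n_perm = 1000L, seed = 1L,
                             weight_exponent = 1) {
  if (n_perm < 1L) config_error("`n_perm` must be >= 1")
  obs <- enrichment_score(ranking, gene_set, weight_exponent)
  N <- nrow(ranking)
  size <- length(obs$hit_indices)
  w_abs <- abs(ranking$weight)^weight_exponent
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(w_abs, sample.int(N, size), N)
    }, numeric(1))
  })
  s <- if (obs$es >= 0) 1 else -1
  same <- if (s > 0) null_es >= 0 else null_es < 0
  if (!any(same)) {
    skinclock_error("no null enrichment score shares the observed sign",
                    "skinclock_nes_undefined_error")
  }
  nes <- obs$es / mean(abs(null_es[same]))
  p <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + sum(same))
  list(es = obs$es, nes = nes, p_value = p, size = size,
       n_perm = as.integer(n_perm))
}

#' Run preranked enrichment for several sources
#'
#' Scores every gene set against every ranking, then truncates each
#' source's table to the `top_k` sets with largest |NES| (ties broken by
#' nominal p, then set name). Sets with no ranked genes are skipped with
#' a warning; sets whose NES is undefined are retained with `NA` NES.
#'
#' @param rankings Named list of [ranked_gene_list()] objects.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param n_perm Permutations per set (default 1000).
#' @param seed Integer base seed; each (source, set) pair gets a derived
#'   child seed.
#' @param top_k Truncation size (default 20).
#' @param weight_exponent Weighting exponent (default 1).
#' @return List with `top` and `full`: named lists (one element per
#'   source) of data.frames with columns `set`, `size`, `es`, `nes`,
#'   `p_value`, `n_perm`, `source`.
#' @export
run_preranked <- function(rankings, collection, n_perm = 1000L, seed = 1L,
                          top_k = 20L, weight_exponent = 1) {
  if (length(rankings) == 0L || length(collection) == 0L) {
    config_error("need at least one ranking and one gene set")
  }
  if (is.null(names(rankings))) {
    names(rankings) <- sprintf("source%02d", seq_along(rankings))
  }
  full <- lapply(seq_along(rankings), function(i) {
    rk <- rankings[[i]]
    rows <- lapply(seq_along(collection), function(j) {
      set_name <- names(collection)[j]
      # seed depends on the set only, so identical rankings supplied as
      # two sources produce identical result tables
      res <- tryCatch(
        permutation_null(rk, collection[[j]], n_perm = n_perm,
                         seed = child_seed(seed, j),
                         weight_exponent = weight_exponent),
        skinclock_empty_overlap_error = function(e) {
          warning(sprintf("set '%s' has no overlap with source '%s'",
                          set_name, names(rankings)[i]), call. = FALSE)
          NULL
        },
        skinclock_nes_undefined_error = function(e) {
          hits <- enrichment_score(rk, collection[[j]], weight_exponent)
          list(es = hits$es, nes = NA_real_, p_value = NA_real_,
               size = length(hits$hit_indices),
               n_perm = as.integer(n_perm))
        })
      if (is.null(res)) return(NULL)
      data.frame(set = set_name, size = res$size, es = res$es,
                 nes = res$nes, p_value = res$p_value,
                 n_perm = res$n_perm, source = names(rankings)[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(full) <- names(rankings)
  top <- lapply(full, function(df) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    ord <- order(-abs(df$nes), df$p_value, df$set, na.last = TRUE)
    out <- df[utils::head(ord, top_k), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  list(top = top, full = full)
}

#' Cross-source pathway consensus
#'
#' Pathways appearing in at least `min_sources` of the truncated
#' per-source tables are retained, annotated with the number of
#' supporting sources and the mean |NES| over them, and sorted by mean
#' |NES| descending.
#'
#' @param per_source_results List of data.frames with columns `set` and
#'   `nes` (e.g. the `top` element of [run_preranked()]).
#' @param min_sources Minimum supporting sources.
#' @return Data.frame `pathway`, `n_sources`, `mean_abs_nes`, `set_size`.
#' @export
consensus <- function(per_source_results, min_sources) {
  K <- length(per_source_results)
  if (K < 1L || min_sources > K) {
    config_error("need 1 <= min_sources <= number of sources")
  }
  all_rows <- do.call(rbind, lapply(per_source_results, function(df) {
    if (is.null(df)) NULL else df[, c("set", "nes", "size")]
  }))
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    return(data.frame(pathway = character(0), n_sources = integer(0),
                      mean_abs_nes = numeric(0), set_size = integer(0)))
  }
  counts <- tapply(all_rows$nes, all_rows$set, length)
  mean_abs <- tapply(abs(all_rows$nes), all_rows$set,
                     function(x) mean(x, na.rm = TRUE))
  sizes <- tapply(all_rows$size, all_rows$set, max)
  keep <- counts >= min_sources
  out <- data.frame(pathway = names(counts)[keep],
                    n_sources = as.integer(counts[keep]),
                    mean_abs_nes = as.numeric(mean_abs[keep]),
                    set_size = as.integer(sizes[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_nes, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
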