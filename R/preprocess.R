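# Probe QC, quantile normalization, and LMR-level feature aggregation.

#' Probe quality-control inputs
#'
#' @param detection_p Probes x samples matrix of detection p-values.
#' @param blocklist Character vector of probe ids to remove (SNP-affected,
#'   cross-hybridizing, ...).
#' @param detection_threshold Removal threshold; a probe whose detection p
#'   exceeds it in any sample is dropped (default 0.01).
#' @return A validated `probe_qc` list.
#' @export
probe_qc <- function(detection_p, blocklist = character(0),
                     detection_threshold = 0.01) {
  if (!is.matrix(detection_p) || is.null(rownames(detection_p))) {
    data_error("`detection_p` must be a matrix with probe rownames")
  }
  if (anyNA(detection_p) || any(detection_p < 0 | detection_p > 1)) {
    data_error("detection p-values must lie in [0, 1]")
  }
  structure(list(detection_p = detection_p,
                 blocklist = unique(as.character(blocklist)),
                 detection_threshold = detection_threshold),
            class = "probe_qc")
}

#' Filter probes by detection p-value and blocklist
#'
#' A probe is removed when its detection p-value exceeds the threshold in
#' any sample, or when it is blocklisted. Probes failing both criteria
#' are counted under the detection reason. Surviving probe order is
#' preserved. The removal report is attached as attribute `removal_report`
#' (counts per reason).
#'
#' @param beta CpG-level beta matrix.
#' @param qc A [probe_qc()] covering all probes in `beta`.
#' @return Filtered beta matrix.
#' @export
filter_probes <- function(beta, qc) {
  probes <- rownames(beta)
  missing <- setdiff(probes, rownames(qc$detection_p))
  if (length(missing) > 0L) {
    data_error(sprintf("%d probes lack detection p-values (e.g. %s)",
                       length(missing), missing[1]))
  }
  max_p <- apply(qc$detection_p[probes, , drop = FALSE], 1L, max)
  fail_det <- max_p > qc$detection_threshold
  fail_block <- probes %in% qc$blocklist & !fail_det
  keep <- !(fail_det | fail_block)
  out <- beta[keep, , drop = FALSE]
  attr(out, "feature_level") <- feature_level(beta)
  attr(out, "removal_report") <- list(
    n_input = length(probes),
    n_kept = sum(keep),
    removed_detection = sum(fail_det),
    removed_blocklist = sum(fail_block))
  out
}

#' Full quantile normalization
#'
#' Forces every sample (column) onto the across-sample mean of order
#' statistics: after normalization all samples share the same sorted value
#' vector and within-sample ranks are preserved. Tied values receive the
#' mean of their tied reference quantiles. Idempotent to numerical
#' tolerance.
#'
#' @param beta Beta matrix (features x samples).
#' @return Normalized beta matrix of the same shape.
#' @export
quantile_normalize <- function(beta) {
  if (length(beta) == 0L || nrow(beta) == 0L || ncol(beta) == 0L) {
    data_error("cannot quantile-normalize an empty matrix")
  }
  if (ncol(beta) == 1L) return(beta)
  ref <- rowMeans(apply(beta, 2L, sort))
  out <- apply(beta, 2L, function(v) {
    assigned <- numeric(length(v))
    assigned[order(v)] <- ref
    stats::ave(assigned, v, FUN = mean)
  })
  dimnames(out) <- dimnames(beta)
  attr(out, "feature_level") <- feature_level(beta)
  out
}

#' Average CpG betas within regions
#'
#' One output feature per region that overlaps at least one CpG present in
#' `beta`; its value per sample is the unweighted mean of the member CpG
#' betas. Regions with no overlapping probes are dropped; their count is
#' attached as attribute `n_dropped`. Output feature ids are
#' `chrom:start-end`.
#'
#' @param beta CpG-level beta matrix.
#' @param regions A [region_set()].
#' @param manifest CpG manifest covering every CpG in `beta`.
#' @return LMR-level beta matrix.
#' @export
lmr_average <- function(beta, regions, manifest) {
  if (identical(feature_level(beta), "lmr")) {
    data_error("`beta` is already at LMR level")
  }
  missing <- setdiff(rownames(beta), manifest$cpg_id)
  if (length(missing) > 0L) {
    data_error(sprintf("%d beta CpGs missing from manifest (e.g. %s)",
                       length(missing), missing[1]))
  }
  mf <- manifest[match(rownames(beta), manifest$cpg_id), , drop = FALSE]
  gr_pos <- GenomicRanges::GRanges(
    mf$chrom, IRanges::IRanges(mf$pos + 1L, width = 1L))
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_pos)
  by_region <- split(S4Vectors::subjectHits(hits),
                     S4Vectors::queryHits(hits))
  covered <- as.integer(names(by_region))
  vals <- do.call(rbind, lapply(by_region, function(rows) {
    colMeans(beta[rows, , drop = FALSE])
  }))
  ids <- sprintf("%s:%d-%d", regions$chrom[covered],
                 regions$start[covered], regions$end[covered])
  rownames(vals) <- ids
  colnames(vals) <- colnames(beta)
  out <- beta_matrix(vals, "lmr")
  attr(out, "n_dropped") <- nrow(regions) - length(covered)
  out
}
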