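# File formats
#
# All on-disk genomic positions are 1-based (array-manifest convention)
# except BED, which is written natively 0-based half-open. Internally every
# position is 0-based and every region is [start, end).

#' Read / write a beta-value matrix as TSV
#'
#' Rows are features (CpG or LMR ids, first column `feature_id`), columns
#' are samples.
#'
#' @param path File path.
#' @param feature_level `"cpg"` or `"lmr"`.
#' @return [read_beta()] returns a validated beta matrix.
#' @export
read_beta <- function(path, feature_level = c("cpg", "lmr")) {
  feature_level <- match.arg(feature_level)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) data_error("beta TSV needs a feature column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  beta_matrix(m, feature_level)
}

#' @rdname read_beta
#' @param beta Beta matrix.
#' @export
write_beta <- function(beta, path) {
  df <- data.frame(feature_id = rownames(beta), beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a CpG manifest
#'
#' On disk: columns `cpg_id`, `chrom`, `pos` (1-based), `gene`
#' (comma-separated symbols, possibly empty). In memory `pos` is 0-based.
#'
#' @param path File path.
#' @return A data.frame with columns `cpg_id`, `chrom`, `pos`, `gene`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene = "character"))
  need <- c("cpg_id", "chrom", "pos", "gene")
  if (!all(need %in% names(df))) {
    data_error(sprintf("manifest must have columns: %s",
                       paste(need, collapse = ", ")))
  }
  df$pos <- as.integer(df$pos) - 1L
  df$gene[is.na(df$gene)] <- ""
  df[need]
}

#' @rdname read_manifest
#' @param manifest Manifest data.frame (0-based `pos`).
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$pos <- as.integer(out$pos) + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write phenotype tables
#'
#' Columns: `sample_id`, `chronological_age`, `wrinkle_grade`, `visual_age`.
#' @param path File path.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) data_error("phenotype table needs sample_id")
  df
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write WGBS-like per-CpG counts
#'
#' On disk: `chrom`, `pos` (1-based), `meth_count`, `total_count`; sorted by
#' position within chromosome. In memory `pos` is 0-based.
#' @param path File path.
#' @return A `wgbs_methylome` data.frame.
#' @export
read_wgbs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "meth_count", "total_count")
  if (!all(need %in% names(df))) {
    data_error(sprintf("WGBS table must have columns: %s",
                       paste(need, collapse = ", ")))
  }
  df$pos <- as.integer(df$pos) - 1L
  wgbs_methylome(df$chrom, df$pos, df$meth_count, df$total_count)
}

#' @rdname read_wgbs
#' @param methylome A `wgbs_methylome`.
#' @export
write_wgbs <- function(methylome, path) {
  out <- as.data.frame(methylome)
  out$pos <- as.integer(out$pos) + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region set as BED and companion TSV
#'
#' BED fields: chrom, start, end, name (`LMR`/`UMR`), score =
#' `round(1000 * mean_methylation)`. The TSV adds `n_cpgs` and the
#' unrounded mean methylation.
#'
#' @param regions Region set data.frame.
#' @param path Output BED path; the TSV goes to `sub(".bed", ".tsv", path)`
#'   unless `tsv_path` is given.
#' @param tsv_path Optional explicit TSV path.
#' @export
write_regions_bed <- function(regions, path, tsv_path = NULL) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start,
                    end = regions$end,
                    name = as.character(regions$class),
                    score = as.integer(round(1000 * regions$mean_methylation)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv_path <- tsv_path %||% sub("\\.bed$", ".tsv", path)
  utils::write.table(regions, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  region_set(df$chrom, df$start, df$end, df$n_cpgs, df$mean_methylation,
             df$class)
}

#' Read a probe blocklist (one probe id per line)
#' @param path File path.
#' @return Character vector of probe ids.
#' @export
read_blocklist <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is tab-separated: set name, description, then member genes.
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) data_error("GMT lines need name, description, >=1 gene")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) data_error("duplicate gene-set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write ranked gene lists in RNK format (gene TAB weight)
#' @param path File path.
#' @return A ranked gene list data.frame (`gene`, `weight`), sorted.
#' @export
read_rnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene", "weight"))
  ranked_gene_list(df$gene, df$weight)
}

#' @rdname read_rnk
#' @param ranking Ranked gene list.
#' @export
write_rnk <- function(ranking, path) {
  utils::write.table(ranking[, c("gene", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
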