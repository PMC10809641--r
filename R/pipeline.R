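# Config-driven orchestration: simulate -> preprocess -> LMR calling ->
# clock training -> evaluation -> enrichment consensus. Every stage can
# be toggled; disabled stages resume from the files earlier runs wrote
# into the output directory. Identical config => identical outputs.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every tunable at its
#' default. User configs (JSON) are merged over this with
#' [read_pipeline_config()].
#'
#' @param seed Global integer seed.
#' @return Nested list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, preprocess = TRUE, lmr = TRUE,
                  train = TRUE, evaluate = TRUE, enrich = TRUE),
    simulate = list(n_subjects = 378L, n_cpgs = 2000L, n_lmrs = 60L,
                    lmr_cpg_range = c(5L, 10L), n_signal_features = 50L,
                    effect_size = 0.005, age_range = c(29, 84),
                    progression_sd = 5, age_coupling = 0,
                    rater_count = 30L, rater_sd_wrinkle = 11.85,
                    rater_sd_age = 6.55, wgbs_mean_coverage = 14,
                    beta_noise_sd = 0.02,
                    expression = list(n_genes = 300L,
                                      n_effect_genes = 30L,
                                      effect_r = 0.5),
                    n_gene_sets = 10L, gene_set_size = 20L,
                    detection_fail_rate = 0.01,
                    blocklist_rate = 0.01),
    lmr = list(meth_cutoff = 0.5, min_cpgs = 4L, smoothing_window = 3L,
               lmr_max_cpgs = 30L, fdr_target = 0.05, n_shuffles = 5L),
    clock = list(k = 10L, p = 0.8, n_bins = 10L, n_lambda = 100L,
                 ratio = 1e-9,
                 outcomes = c("wrinkle_grade", "visual_age", "progression"),
                 levels = c("cpg", "lmr")),
    enrichment = list(p_cut = 0.05, n_perm = 1000L, top_k = 20L,
                      min_sources = 2L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration (JSON), merged over the defaults
#' @param path JSON file path.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config not found: %s", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(default_pipeline_config(), user)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Build a synthetic gene-set collection over the cohort's gene pool:
# background sets are random draws; the first two sets are seeded with
# genes annotated to the planted signal CpGs so that enrichment has
# something to find.
synth_gene_sets <- function(cohort, n_sets, set_size, extra_genes, seed) {
  pairs <- manifest_gene_pairs(cohort$manifest)
  pool <- sort(unique(c(pairs$gene, extra_genes)))
  signal_genes <- sort(unique(
    pairs$gene[pairs$cpg_id %in% cohort$truth$signal_feature_ids]))
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      if (i <= 2L && length(signal_genes) > 0L) {
        core <- signal_genes[sample.int(length(signal_genes),
                                        min(length(signal_genes),
                                            ceiling(set_size / 2)))]
        unique(c(core, sample(pool, set_size - length(core) + 2L)))
      } else {
        sample(pool, set_size)
      }
    })
    names(sets) <- sprintf("TOY_PATHWAY_%02d", seq_len(n_sets))
    sets
  })
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing standard-format outputs
#' plus a `run_manifest.json` sidecar with the config hash, seed, stage
#' timings, and per-file MD5 hashes. Disabled stages are resumed from
#' files already present in `out_dir`. A stage failure aborts with the
#' failing stage named; outputs of completed stages are retained.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   path to a JSON config.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pth <- function(...) file.path(out_dir, ...)
  seed <- as.integer(config$seed)
  timings <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("stage %-10s done (%.1fs)", name, timings[[name]])
    res
  }

  on <- function(...) {
    any(vapply(c(...), function(s) isTRUE(config$stages[[s]]), logical(1)))
  }
  cohort <- NULL; wgbs <- NULL; expr <- NULL; qc <- NULL; sets <- NULL
  if (isTRUE(config$stages$simulate)) {
    run_stage("simulate", function() {
      sc <- config$simulate
      cfg <- sim_config(n_subjects = sc$n_subjects, n_cpgs = sc$n_cpgs,
                        n_lmrs = sc$n_lmrs,
                        lmr_cpg_range = sc$lmr_cpg_range,
                        n_signal_features = sc$n_signal_features,
                        effect_size = sc$effect_size,
                        age_range = sc$age_range,
                        progression_sd = sc$progression_sd,
                        age_coupling = sc$age_coupling,
                        rater_count = sc$rater_count,
                        rater_sd_wrinkle = sc$rater_sd_wrinkle,
                        rater_sd_age = sc$rater_sd_age,
                        wgbs_mean_coverage = sc$wgbs_mean_coverage,
                        beta_noise_sd = sc$beta_noise_sd,
                        seed = child_seed(seed, 101L))
      cohort <<- simulate_cohort(cfg)
      wgbs <<- simulate_wgbs(cohort$truth$planted_lmr_regions,
                             cohort$manifest,
                             mean_coverage = sc$wgbs_mean_coverage,
                             seed = child_seed(seed, 102L))
      ex <- sc$expression
      expr <<- simulate_expression(cohort$truth$true_progression,
                                   n_genes = ex$n_genes,
                                   n_effect_genes = ex$n_effect_genes,
                                   effect_r = ex$effect_r,
                                   seed = child_seed(seed, 103L))
      qc <<- with_seed(child_seed(seed, 104L), {
        probes <- rownames(cohort$beta)
        np <- length(probes)
        det <- matrix(stats::runif(np * 3L, 0, 0.005), nrow = np,
                      dimnames = list(probes, sprintf("QC%02d", 1:3)))
        n_fail <- max(1L, round(sc$detection_fail_rate * np))
        det[sample.int(np, n_fail), 1L] <- stats::runif(n_fail, 0.02, 0.5)
        block <- sort(sample(probes,
                             max(1L, round(sc$blocklist_rate * np))))
        probe_qc(det, block)
      })
      sets <<- synth_gene_sets(cohort, config$simulate$n_gene_sets,
                               config$simulate$gene_set_size,
                               rownames(expr), child_seed(seed, 105L))
      write_beta(cohort$beta, pth("beta_raw.tsv"))
      write_phenotypes(cohort$phenotypes, pth("phenotypes.tsv"))
      write_manifest(cohort$manifest, pth("manifest.tsv"))
      write_wgbs(wgbs, pth("wgbs.tsv"))
      utils::write.table(
        data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
        pth("expression.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(chronological_age = cohort$truth$chronological_age,
             true_progression = cohort$truth$true_progression,
             true_visual_age = cohort$truth$true_visual_age,
             true_wrinkle = cohort$truth$true_wrinkle,
             signal_feature_ids = cohort$truth$signal_feature_ids),
        pth("truth.json"), digits = NA)
      write_regions_bed(cohort$truth$planted_lmr_regions,
                        pth("planted_lmrs.bed"))
      utils::write.table(
        data.frame(probe_id = rownames(qc$detection_p), qc$detection_p,
                   check.names = FALSE),
        pth("detection_p.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      writeLines(qc$blocklist, pth("blocklist.txt"))
      write_gmt(sets, pth("gene_sets.gmt"))
      NULL
    })
  } else if (on("preprocess", "lmr", "train", "evaluate", "enrich")) {
    cohort <- list(beta = read_beta(pth("beta_raw.tsv"), "cpg"),
                   phenotypes = read_phenotypes(pth("phenotypes.tsv")),
                   manifest = read_manifest(pth("manifest.tsv")))
    if (on("lmr")) wgbs <- read_wgbs(pth("wgbs.tsv"))
    if (on("enrich")) {
      edf <- utils::read.delim(pth("expression.tsv"), check.names = FALSE)
      expr <- as.matrix(edf[, -1L, drop = FALSE])
      rownames(expr) <- edf[[1L]]
      sets <- read_gmt(pth("gene_sets.gmt"))
    }
    if (on("preprocess")) {
      ddf <- utils::read.delim(pth("detection_p.tsv"), check.names = FALSE)
      det <- as.matrix(ddf[, -1L, drop = FALSE])
      rownames(det) <- ddf[[1L]]
      qc <- probe_qc(det, read_blocklist(pth("blocklist.txt")))
    }
  }

  beta_norm <- NULL
  if (isTRUE(config$stages$preprocess)) {
    beta_norm <- run_stage("preprocess", function() {
      filtered <- filter_probes(cohort$beta, qc)
      jsonlite::write_json(attr(filtered, "removal_report"),
                           pth("removal_report.json"), auto_unbox = TRUE)
      normed <- quantile_normalize(filtered)
      write_beta(normed, pth("beta_norm.tsv"))
      normed
    })
  } else if (on("lmr", "train", "evaluate", "enrich")) {
    beta_norm <- read_beta(pth("beta_norm.tsv"), "cpg")
  }

  lmrs <- NULL; beta_lmr <- NULL
  if (isTRUE(config$stages$lmr)) {
    lmrs <- run_stage("lmr", function() {
      lc <- config$lmr
      params <- seg_params(meth_cutoff = lc$meth_cutoff,
                           min_cpgs = lc$min_cpgs,
                           smoothing_window = lc$smoothing_window,
                           lmr_max_cpgs = lc$lmr_max_cpgs,
                           fdr_target = lc$fdr_target,
                           n_shuffles = lc$n_shuffles,
                           seed = child_seed(seed, 201L))
      cal <- calibrate_fdr(wgbs, params)
      utils::write.table(cal$fdr_table, pth("lmr_fdr_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      params$meth_cutoff <- cal$meth_cutoff
      params$min_cpgs <- cal$min_cpgs
      segs <- classify_segments(segment_hypomethylated(wgbs, params),
                                params$lmr_max_cpgs)
      kept <- intersect_with_probes(segs, cohort$manifest)
      write_regions_bed(segs, pth("segments.bed"))
      write_regions_bed(kept, pth("lmrs.bed"))
      kept
    })
  } else if (on("train", "evaluate", "enrich")) {
    lmrs <- read_regions_tsv(pth("lmrs.tsv"))
  }
  if (on("lmr", "train", "evaluate", "enrich")) {
    beta_lmr <- lmr_average(beta_norm, lmrs, cohort$manifest)
    write_beta(beta_lmr, pth("beta_lmr.tsv"))
  }

  chash <- config_hash(config)
  models <- list()
  if (isTRUE(config$stages$train)) {
    run_stage("train", function() {
      cc <- config$clock
      combos <- expand.grid(outcome = unlist(cc$outcomes),
                            level = unlist(cc$levels),
                            stringsAsFactors = FALSE)
      for (i in seq_len(nrow(combos))) {
        okind <- combos$outcome[i]; lvl <- combos$level[i]
        b <- if (lvl == "lmr") beta_lmr else beta_norm
        y <- make_outcome(cohort$phenotypes, okind)
        part <- stratified_partition(y, p = cc$p, n_bins = cc$n_bins,
                                     seed = child_seed(seed, 301L + i))
        Xtr <- t(b[, part$train_ids, drop = FALSE])
        fit <- cv_train(Xtr, y[part$train_ids], k = cc$k,
                        lambda_grid = lambda_path(Xtr, y[part$train_ids],
                                                  n_lambda = cc$n_lambda,
                                                  ratio = cc$ratio),
                        seed = child_seed(seed, 401L + i),
                        outcome_kind = okind, feature_level = lvl)
        tag <- sprintf("%s_%s", okind, lvl)
        write_clock_model(fit$model, pth(sprintf("model_%s.json", tag)),
                          provenance = list(config_hash = chash,
                                            seed = seed,
                                            partition_seed = part$seed))
        write_cv_report(fit$cv, pth(sprintf("cv_%s.tsv", tag)))
        jsonlite::write_json(list(train_ids = part$train_ids,
                                  test_ids = part$test_ids),
                             pth(sprintf("partition_%s.json", tag)))
        models[[tag]] <<- list(model = fit$model, partition = part)
      }
      NULL
    })
  } else if (isTRUE(config$stages$evaluate) ||
             isTRUE(config$stages$enrich)) {
    cc <- config$clock
    for (okind in unlist(cc$outcomes)) {
      for (lvl in unlist(cc$levels)) {
        tag <- sprintf("%s_%s", okind, lvl)
        mp <- pth(sprintf("model_%s.json", tag))
        pp <- pth(sprintf("partition_%s.json", tag))
        if (file.exists(mp) && file.exists(pp)) {
          part <- jsonlite::read_json(pp, simplifyVector = TRUE)
          models[[tag]] <- list(model = read_clock_model(mp),
                                partition = part)
        }
      }
    }
  }

  if (isTRUE(config$stages$evaluate)) {
    run_stage("evaluate", function() {
      for (tag in names(models)) {
        m <- models[[tag]]
        lvl <- m$model$feature_level
        b <- if (lvl == "lmr") beta_lmr else beta_norm
        btest <- b[, m$partition$test_ids, drop = FALSE]
        attr(btest, "feature_level") <- lvl
        rep <- validate_clock(m$model, btest, cohort$phenotypes,
                              dataset_label = "test")
        write_validation_report(rep, pth(sprintf("validation_%s", tag)))
      }
      NULL
    })
  }

  if (isTRUE(config$stages$enrich)) {
    run_stage("enrich", function() {
      ec <- config$enrichment
      prog_tag <- "progression_lmr"
      if (is.null(models[[prog_tag]])) {
        model_error("enrichment needs the LMR-level progression clock")
      }
      m <- models[[prog_tag]]
      test_ids <- m$partition$test_ids
      blmr <- beta_lmr[, test_ids, drop = FALSE]
      attr(blmr, "feature_level") <- "lmr"
      preds <- stats::predict(m$model, blmr)
      bcpg <- beta_norm[, test_ids, drop = FALSE]
      attr(bcpg, "feature_level") <- "cpg"
      rankings <- list(
        coefficient = rank_from_coefficients(m$model, cohort$manifest),
        methylation_test = rank_from_methylation_correlation(
          bcpg, preds, cohort$manifest, p_cut = ec$p_cut),
        expression_test = rank_from_expression_correlation(
          expr[, test_ids, drop = FALSE], preds, p_cut = ec$p_cut))
      for (nm in names(rankings)) {
        write_rnk(rankings[[nm]], pth(sprintf("ranking_%s.rnk", nm)))
      }
      res <- suppressWarnings(
        run_preranked(rankings, sets, n_perm = ec$n_perm,
                      seed = child_seed(seed, 501L),
                      top_k = ec$top_k))
      full_tab <- do.call(rbind, res$full)
      utils::write.table(full_tab, pth("enrichment_full.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      top_tab <- do.call(rbind, res$top)
      utils::write.table(top_tab, pth("enrichment_top.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cons <- consensus(res$top, min_sources = ec$min_sources)
      utils::write.table(cons, pth("consensus.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      NULL
    })
  }

  outputs <- setdiff(list.files(out_dir), "run_manifest.json")
  manifest <- list(config_hash = chash, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("skinclock")),
                   stage_timings_s = timings,
                   output_md5 = as.list(tools::md5sum(
                     file.path(out_dir, outputs))))
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, pth("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
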