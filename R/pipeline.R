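#' Configuration for the end-to-end analysis
#'
#' Collects every knob of the synthetic cohort and the analysis in one
#' validated list. Defaults describe the reference synthetic study: 20
#' subjects, 360 parcels, 24 conditions x 3 blocks of 18 s at TR = 0.72 s
#' (run length about 2900 TRs, comfortably exceeding the roughly 1200 FIR
#' columns), FIR extent 25 TRs past block offset, and 1000 surrogate maps
#' per statistical test.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_subjects Cohort size.
#' @param n_parcels Number of parcels.
#' @param n_conditions Task conditions.
#' @param blocks_per_condition Blocks per condition.
#' @param block_len_s,rest_len_s Block / inter-block rest duration (seconds).
#' @param tr_s Sampling interval (seconds).
#' @param n_drop Initial frames trimmed per run.
#' @param fir_post_offset_lags FIR extent past block offset (TRs).
#' @param acf_max_lag ACF extent for timescale fitting (TRs).
#' @param n_surrogates Surrogates per map-correlation test.
#' @param n_boot Bootstrap draws per confidence interval.
#' @param approach `"both"`, `"glm"` or `"peak"`.
#' @param positive_only Threshold FC matrices at zero before degree
#'   computation.
#' @param confound_weight Amplitude of injected nuisance artifact.
#' @param effect Planted effect structure, see [effect_config()].
#' @param prop_unimodal Fraction of parcels labelled unimodal.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 20, n_parcels = 360,
                            n_conditions = 24, blocks_per_condition = 3,
                            block_len_s = 18, rest_len_s = 10.8, tr_s = 0.72,
                            n_drop = 5, fir_post_offset_lags = 25,
                            acf_max_lag = 50, n_surrogates = 1000,
                            n_boot = 1000, approach = c("both", "glm", "peak"),
                            positive_only = FALSE, confound_weight = 0.3,
                            effect = effect_config(), prop_unimodal = 1/3) {
  approach <- match.arg(approach)
  cfg <- list(seed = check_scalar_int(seed, "seed"),
              n_subjects = check_scalar_int(n_subjects, "n_subjects", min = 3),
              n_parcels = check_scalar_int(n_parcels, "n_parcels", min = 10),
              n_conditions = check_scalar_int(n_conditions, "n_conditions", min = 1),
              blocks_per_condition = check_scalar_int(blocks_per_condition,
                                                      "blocks_per_condition", min = 1),
              block_len_s = block_len_s, rest_len_s = rest_len_s, tr_s = tr_s,
              n_drop = check_scalar_int(n_drop, "n_drop", min = 0),
              fir_post_offset_lags = check_scalar_int(fir_post_offset_lags,
                                                      "fir_post_offset_lags", min = 0),
              acf_max_lag = check_scalar_int(acf_max_lag, "acf_max_lag", min = 4),
              n_surrogates = check_scalar_int(n_surrogates, "n_surrogates", min = 1),
              n_boot = check_scalar_int(n_boot, "n_boot", min = 1),
              approach = approach, positive_only = isTRUE(positive_only),
              confound_weight = confound_weight,
              effect = do.call(effect_config, effect),
              prop_unimodal = prop_unimodal)
  class(cfg) <- "pipeline_config"
  cfg
}

# Preprocess one raw run: trim/demean/detrend the data and the confound
# traces on the same frames, then regress the 64-regressor nuisance design.
preprocess_run <- function(ts_raw, confounds, n_drop) {
  ts <- trim_demean_detrend(ts_raw, n_drop)
  trim <- function(m) m[(n_drop + 1L):nrow(m), , drop = FALSE]
  design <- assemble_nuisance(
    build_motion_regressors(trim(confounds$motion)),
    acompcor(trim(confounds$wm_ts), 5),
    acompcor(trim(confounds$vent_ts), 5))
  nuisance_regress(ts, design)
}

#' Run the full localized-versus-distributed analysis on a synthetic cohort
#'
#' Simulates a cohort from planted ground truth and runs every stage:
#' nuisance preprocessing, canonical-HRF activation GLM, FIR task regression
#' and interval-matched task/rest FC with weighted-degree change, the
#' regression-free block-peak variant, per-subject intrinsic-timescale maps,
#' activity flow mapping with multiple-regression FC, partition contrasts,
#' and the surrogate-map association table across all brain-map pairs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, group maps, the association
#'   table, and a provenance record (resolved config, seeds, content
#'   fingerprints) are written there as TSV/JSON.
#' @param verbose Print per-stage progress.
#' @return Object of class `cortexflow_analysis`; see [print.cortexflow_analysis()].
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  stage <- "synthesis"
  res <- tryCatch({
    geometry <- generate_geometry(config$n_parcels, seed = sub_seed(seed, 1))
    gt <- generate_ground_truth(config$n_parcels, config$n_conditions,
                                config = config$effect,
                                seed = sub_seed(seed, 2), geometry = geometry)
    design <- generate_block_design(config$n_conditions,
                                    config$blocks_per_condition,
                                    config$block_len_s, config$rest_len_s,
                                    config$tr_s)
    design_t <- shift_design(design, -config$n_drop * config$tr_s,
                             n_tr = design$n_tr - config$n_drop)
    intervals <- intervals_from_design(design_t)
    partition <- partition_from_hierarchy(gt$hierarchy, config$prop_unimodal)

    do_glm <- config$approach %in% c("both", "glm")
    do_peak <- config$approach %in% c("both", "peak")
    n_s <- config$n_subjects
    acts <- vector("list", n_s)
    sub_act_glm <- sub_act_peak <- sub_dfc_glm <- sub_dfc_peak <-
      sub_mae <- matrix(NA_real_, n_s, config$n_parcels)
    tau_maps <- vector("list", n_s)

    for (s in seq_len(n_s)) {
      stage <- sprintf("subject %d", s)
      say("subject %d / %d", s, n_s)
      rest_raw <- simulate_rest_timeseries(gt, design$n_tr, config$tr_s,
                                           seed = sub_seed(seed, 100 + s))
      task_raw <- simulate_task_timeseries(gt, design,
                                           seed = sub_seed(seed, 200 + s))
      conf_rest <- generate_confounds(design$n_tr, sub_seed(seed, 300 + s))
      conf_task <- generate_confounds(design$n_tr, sub_seed(seed, 400 + s))
      rest_raw <- inject_confounds(rest_raw, conf_rest, config$confound_weight,
                                   seed = sub_seed(seed, 500 + s))
      task_raw <- inject_confounds(task_raw, conf_task, config$confound_weight,
                                   seed = sub_seed(seed, 600 + s))
      rest <- preprocess_run(rest_raw, conf_rest, config$n_drop)
      task <- preprocess_run(task_raw, conf_task, config$n_drop)

      act <- fit_activation_glm(task, build_condition_regressors(design_t),
                                subject_id = sprintf("sub%03d", s))
      acts[[s]] <- act
      sub_act_glm[s, ] <- rowMeans(abs(act$betas))

      if (do_glm) {
        fir_task <- fir_regress(task, design_t, config$fir_post_offset_lags)
        task_fc <- correlation_fc(fir_task, intervals)
        rest_fc <- matched_rest_fc(rest, design_t, config$fir_post_offset_lags)
        sub_dfc_glm[s, ] <- fc_change_map(task_fc, rest_fc,
                                          config$positive_only)
      }
      if (do_peak) {
        baselined <- baseline_to_interblock_rest(task, design_t)
        pk <- extract_block_peaks(baselined, design_t)
        sub_act_peak[s, ] <- peak_activation_map(pk)
        rest_pk_fc <- pseudo_block_rest_peak_fc(rest, design_t)
        sub_dfc_peak[s, ] <- fc_change_map(peak_fc(pk), rest_pk_fc,
                                           config$positive_only)
      }
      tau_maps[[s]] <- subject_timescale_map(rest, config$tr_s,
                                             config$acf_max_lag)
      mfc <- multreg_fc(rest)
      sub_mae[s, ] <- actflow_mae(actflow_predict(act$betas, mfc))
    }

    stage <- "group maps"
    group <- list(hierarchy = gt$hierarchy,
                  myelin = gt$myelin_true,
                  timescale = group_timescale_map(tau_maps),
                  actflow_mae = colMeans(sub_mae),
                  activation_glm = group_activation_magnitude(acts))
    if (do_glm) group$fc_change_glm <- colMeans(sub_dfc_glm)
    if (do_peak) {
      group$activation_peak <- colMeans(sub_act_peak)
      group$fc_change_peak <- colMeans(sub_dfc_peak)
    }

    stage <- "association table"
    say("association table (%d surrogates per map)", config$n_surrogates)
    association <- association_table(group, geometry, config,
                                     do_glm = do_glm, do_peak = do_peak)

    stage <- "partition contrasts"
    contrast_rows <- list(
      list(measure = "activation", approach = "glm", maps = sub_act_glm),
      if (do_glm) list(measure = "fc_change", approach = "glm", maps = sub_dfc_glm),
      if (do_peak) list(measure = "activation", approach = "peak", maps = sub_act_peak),
      if (do_peak) list(measure = "fc_change", approach = "peak", maps = sub_dfc_peak),
      list(measure = "timescale", approach = "shared",
           maps = t(vapply(tau_maps, `[[`, numeric(config$n_parcels), "tau"))),
      list(measure = "actflow_mae", approach = "shared", maps = sub_mae))
    contrast_rows <- Filter(Negate(is.null), contrast_rows)
    contrasts <- do.call(rbind, lapply(contrast_rows, function(r) {
      m <- r$maps
      m[!is.finite(m)] <- NA
      ct <- partition_contrast(m, partition, na.rm = TRUE)
      data.frame(measure = r$measure, approach = r$approach,
                 mean_diff = ct$mean_diff, t = ct$t, df = ct$df, p = ct$p)
    }))

    out <- list(config = config, ground_truth = gt, design = design_t,
                partition = partition, group_maps = group,
                subject_maps = list(activation_glm = sub_act_glm,
                                    activation_peak = if (do_peak) sub_act_peak,
                                    fc_change_glm = if (do_glm) sub_dfc_glm,
                                    fc_change_peak = if (do_peak) sub_dfc_peak,
                                    actflow_mae = sub_mae),
                association = association, contrasts = contrasts)
    class(out) <- "cortexflow_analysis"
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage [%s]: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

# All 15 pairwise associations among the six group maps, per approach, each
# tested against the surrogate ensemble of the pair's first map.
association_table <- function(group, geometry, config, do_glm, do_peak) {
  shared <- c("hierarchy", "activation", "fc_change", "timescale", "myelin",
              "actflow_mae")
  resolve <- function(name, approach) {
    switch(name,
           activation = paste0("activation_", approach),
           fc_change = paste0("fc_change_", approach),
           name)
  }
  ensembles <- new.env(parent = emptyenv())
  ens_seed <- 0L
  get_ensemble <- function(key, map) {
    if (is.null(ensembles[[key]])) {
      ens_seed <<- ens_seed + 1L
      ensembles[[key]] <- surrogate_maps(map, geometry,
                                         n_surrogates = config$n_surrogates,
                                         seed = sub_seed(config$seed, 900 + ens_seed))
    }
    ensembles[[key]]
  }
  rows <- list()
  boot_i <- 0L
  for (approach in c(if (do_glm) "glm", if (do_peak) "peak")) {
    pairs <- utils::combn(shared, 2L)
    for (pi in seq_len(ncol(pairs))) {
      a_key <- resolve(pairs[1L, pi], approach)
      b_key <- resolve(pairs[2L, pi], approach)
      map_a <- group[[a_key]]; map_b <- group[[b_key]]
      test <- sa_perm_correlation_test(map_a, map_b, get_ensemble(a_key, map_a))
      boot_i <- boot_i + 1L
      ci <- bootstrap_spearman_ci(map_a, map_b, n_boot = config$n_boot,
                                  seed = sub_seed(config$seed, 700 + boot_i))
      rows[[length(rows) + 1L]] <- data.frame(
        approach = approach, map_a = pairs[1L, pi], map_b = pairs[2L, pi],
        rho = test$rho, p = test$p, ci_low = ci[1L], ci_high = ci[2L],
        n_surrogates = test$n_surrogates)
    }
  }
  do.call(rbind, rows)
}

# Serialize group maps, tables and a provenance record to `out_dir`.
write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$group_maps))
    write_brain_map(res$group_maps[[nm]],
                    file.path(out_dir, paste0("map_", nm, ".tsv")))
  utils::write.table(res$association, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$contrasts, file.path(out_dir, "contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- res$config
  class(cfg) <- NULL
  provenance <- list(
    config = cfg,
    hashes = lapply(res$group_maps, content_hash))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cortexflow_analysis <- function(x, ...) {
  cat(sprintf("<cortexflow_analysis> %d subjects, %d parcels, %d conditions\n",
              x$config$n_subjects, x$config$n_parcels, x$config$n_conditions))
  cat("\nPartition contrasts (transmodal - unimodal):\n")
  print(x$contrasts, row.names = FALSE, digits = 3)
  cat("\nAssociations (Spearman rho, surrogate-map p):\n")
  print(x$association[, c("approach", "map_a", "map_b", "rho", "p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
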