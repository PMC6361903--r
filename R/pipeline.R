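#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic run. One base seed
#' fans out to per-stage seeds by fixed offsets (+1 cohort, +2 model, +3
#' clustering), so a stage can be re-run in isolation and still match the
#' full run.
#'
#' @param n_patients cohort size.
#' @param threshold SUV segmentation threshold.
#' @param min_cc minimum analyzable metabolic volume, cc.
#' @param n_bins gray levels for discretization.
#' @param selected_features model/clustering feature set; defaults to the 5
#'   most predictive features of refractory mediastinal disease: GlobalMax,
#'   Volume, InformationMeasureCorr1, InformationMeasureCorr2,
#'   InverseVariance.
#' @param mode `"rotate"` or `"single"` holdout scheme.
#' @param n_stages boosting stages.
#' @param max_rounds cap on rotation rounds.
#' @param n_boot bootstrap resamples for CIs.
#' @param k number of prognostic groups.
#' @param seed base seed.
#' @param model a [class_model] for the synthetic cohort.
#' @param grid_shape,spacing phantom grid per patient.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 169L, threshold = 2.5, min_cc = 5.0,
                            n_bins = 64L,
                            selected_features = c("GlobalMax", "Volume",
                                                  "InformationMeasureCorr1",
                                                  "InformationMeasureCorr2",
                                                  "InverseVariance"),
                            mode = "rotate", n_stages = 50L,
                            max_rounds = Inf, n_boot = 2000L, k = 5L,
                            seed = 7L, model = class_model(),
                            grid_shape = c(32L, 32L, 32L),
                            spacing = c(4, 4, 4)) {
  stopifnot(n_patients >= 4, threshold > 0, min_cc > 0, n_bins >= 2,
            n_stages >= 1, k >= 1,
            all(selected_features %in% c(feature_names(), "tlg")))
  structure(list(n_patients = as.integer(n_patients), threshold = threshold,
                 min_cc = min_cc, n_bins = as.integer(n_bins),
                 selected_features = selected_features, mode = mode,
                 n_stages = as.integer(n_stages), max_rounds = max_rounds,
                 n_boot = as.integer(n_boot), k = as.integer(k),
                 seed = as.integer(seed), model = model,
                 grid_shape = as.integer(grid_shape), spacing = spacing),
            class = "pipeline_config")
}

#' Extract the per-site feature table of a cohort
#'
#' Segments every site of every patient at the SUV threshold, drops sites
#' below the minimum metabolic volume (each exclusion is logged), and
#' extracts the 33-feature vector per retained site. TLG is carried along
#' as an extra column for the baseline comparison.
#'
#' @param patients list of [patient_record] objects.
#' @param threshold,min_cc,n_bins see [pipeline_config()].
#' @return data.frame: `patient_id`, `site_label`, `mtv_cc`, `suv_mean`,
#'   `tlg`, the 33 feature columns, and the outcome flags.
#' @export
extract_cohort_features <- function(patients, threshold = 2.5, min_cc = 5.0,
                                    n_bins = 64L) {
  rows <- list()
  for (pr in patients) {
    for (s in pr$sites) {
      seg <- threshold_segment(s$vol, s$mask, threshold)
      if (seg$mtv_cc < min_cc) {
        message(sprintf("excluding %s site '%s': MTV %.3f cc < %.3f cc",
                        pr$patient_id, seg$site_label, seg$mtv_cc, min_cc))
        next
      }
      fv <- extract_feature_vector(s$vol, s$mask, threshold = threshold,
                                   min_cc = min_cc, n_bins = n_bins, seg = seg)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient_id = pr$patient_id, site_label = seg$site_label,
                   mtv_cc = seg$mtv_cc, suv_mean = seg$suv_mean,
                   tlg = seg$tlg, stringsAsFactors = FALSE),
        as.data.frame(as.list(fv)),
        data.frame(refractory = pr$refractory, relapsed = pr$relapsed,
                   death_from_hl = pr$death_from_hl)
      )
    }
  }
  if (length(rows) == 0)
    stop("no analyzable sites: every site fell below the minimum volume")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic pipeline
#'
#' Phantom cohort generation, threshold segmentation, small-site exclusion,
#' 33-feature extraction, outcome-stratified leave-2-groups-out boosted-SVM
#' evaluation with single-feature ROC baselines (MTV, TLG, SUVmax), and
#' hierarchical clustering into prognostic groups. All outputs are written
#' to `out_dir` (`features.csv`, `outcomes.csv`, `eval.json`, `groups.csv`,
#' `summary.csv`, `config.yaml`, `log.txt`) and are byte-identical across
#' runs with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return Invisibly, a list: `features` (per-site table), `eval`
#'   (boosted-model `eval_result`), `baselines` (named list of
#'   `eval_result`), `clusters` (`cluster_result`), `summary` (group
#'   summary data.frame).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  note("cohort: n=%d, seed=%d", config$n_patients, config$seed + 1L)
  coh <- generate_cohort(config$model, config$n_patients,
                         seed = config$seed + 1L,
                         grid_shape = config$grid_shape,
                         spacing = config$spacing)

  feats <- withCallingHandlers(
    extract_cohort_features(coh$patients, threshold = config$threshold,
                            min_cc = config$min_cc, n_bins = config$n_bins),
    message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  note("features: %d analyzable sites, %d columns", nrow(feats), ncol(feats))

  outcomes <- feats[, c("patient_id", "site_label", "refractory", "relapsed",
                        "death_from_hl")]
  if (sum(outcomes$refractory) < 2)
    stop("fewer than 2 refractory cases survived site exclusion")

  folds <- make_refractory_folds(outcomes, seed = config$seed + 2L)
  ev <- evaluate_leave_2_groups_out(feats, outcomes, folds,
                                    feature_names = config$selected_features,
                                    mode = config$mode,
                                    n_stages = config$n_stages,
                                    max_rounds = config$max_rounds,
                                    n_boot = config$n_boot,
                                    seed = config$seed + 2L)
  note("model: AUC %.3f (%.3f-%.3f), error rate %.3f",
       ev$auc, ev$ci_low, ev$ci_high, ev$total_error_rate)

  baselines <- list(
    mtv = single_feature_auc(feats$Volume, outcomes$refractory,
                             n_boot = config$n_boot, seed = config$seed + 2L),
    tlg = single_feature_auc(feats$tlg, outcomes$refractory,
                             n_boot = config$n_boot, seed = config$seed + 2L),
    suv_max = single_feature_auc(feats$GlobalMax, outcomes$refractory,
                                 n_boot = config$n_boot,
                                 seed = config$seed + 2L)
  )
  note("baselines: MTV AUC %.3f, TLG AUC %.3f, SUVmax AUC %.3f",
       baselines$mtv$auc, baselines$tlg$auc, baselines$suv_max$auc)

  z <- zscore_features(feats, config$selected_features)
  cl <- hierarchical_groups(z, k = config$k)
  summ <- summarize_groups(cl$labels, outcomes)
  note("clustering: %d groups, sizes %s", config$k,
       paste(summ$n, collapse = "/"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    write_outcomes(outcomes, file.path(out_dir, "outcomes.csv"))
    eval_json <- list(
      model = list(auc = ev$auc, ci_low = ev$ci_low, ci_high = ev$ci_high,
                   total_error_rate = ev$total_error_rate),
      baselines = lapply(baselines, function(b)
        list(auc = b$auc, ci_low = b$ci_low, ci_high = b$ci_high))
    )
    jsonlite::write_json(eval_json, file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(patient_id = outcomes$patient_id,
                                group = cl$labels),
                     file.path(out_dir, "groups.csv"), row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$model <- unclass(cfg$model)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  invisible(list(features = feats, eval = ev, baselines = baselines,
                 clusters = cl, summary = summ))
}
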