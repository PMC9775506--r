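#' Extract all 36 features of one participant
#'
#' Runs preprocessing (epoch, baseline-correct, artifact-screen) and feature
#' extraction (12 time-domain SP features + 24 ERSP features) per task
#' period for a single recording.
#'
#' @param recording A `gsat_recording`.
#' @param sp_window SP feature window in ms (inclusive).
#' @param artifact_threshold Epoch rejection threshold in microvolts.
#' @param stft_window_ms,stft_hop_ms,freq_res STFT parameters.
#' @param average_domain ERSP trial-combination order, see [compute_ersp()].
#' @param filter Optional band-pass for [epoch_signal()].
#' @param periods Task periods to featurize (default: all present).
#' @return `data.frame` with one row per period: `participant`, `group`,
#'   `period`, then the 36 feature columns in canonical order.
#' @export
featurize_recording <- function(recording, sp_window = c(460, 700),
                                artifact_threshold = 100,
                                stft_window_ms = 250, stft_hop_ms = 20,
                                freq_res = 0.5, average_domain = "power",
                                filter = NULL, periods = NULL) {
  ep <- epoch_signal(recording, filter = filter)
  ep <- baseline_correct(ep)
  ep <- reject_artifacts(ep, artifact_threshold)
  if (is.null(periods)) periods <- sort(unique(ep$period))
  rows <- lapply(periods, function(pd) {
    go_erp <- average_erp(ep, "go", pd)
    nogo_erp <- average_erp(ep, "nogo", pd)
    td <- time_domain_features(go_erp, nogo_erp, sp_window)
    go_ersp <- compute_ersp(ep, "go", pd, window_ms = stft_window_ms,
                            hop_ms = stft_hop_ms, freq_res = freq_res,
                            average_domain = average_domain)
    nogo_ersp <- compute_ersp(ep, "nogo", pd, window_ms = stft_window_ms,
                              hop_ms = stft_hop_ms, freq_res = freq_res,
                              average_domain = average_domain)
    tf <- tf_features(go_ersp, nogo_ersp, window = sp_window)
    cbind(data.frame(participant = recording$participant_id,
                     group = recording$group_label, period = pd,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(c(td, tf))))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_rejected") <- attr(ep, "n_rejected")
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generate -> preprocess -> featurize -> select -> evaluate, end to end and
#' seeded. Participants are generated and featurized one at a time (the raw
#' cohort is never held in memory). Per-period feature tables (participants
#' x 36 features) are assembled, then [evaluate_all()] runs feature
#' selection and leave-one-out evaluation of every classifier.
#'
#' When `out_dir` is given, the run writes: per-period feature CSVs, the
#' behavioral summary CSV, per-participant events TSVs (first participant
#' only unless `write_all_events`), rankings and the evaluation report as
#' JSON, and a manifest listing every artifact with its MD5 content hash,
#' the serialized configuration and package version. Re-running with an
#' identical configuration reproduces identical artifacts.
#'
#' @param config A [cohort_config()].
#' @param specs Named list of [classifier_spec()]s.
#' @param out_dir Optional output directory (created if missing).
#' @param k_top,relieff_k,selection_scope Selection settings, see
#'   [evaluate_all()].
#' @param write_all_events Write every participant's events TSV (default:
#'   only the first, as a format sample).
#' @param ... Passed to [featurize_recording()].
#' @return List with `report` (a `gsat_report`), `tables` (per-period
#'   feature data frames), `behavior` (group x period omission/RT summary),
#'   `labels`, `config`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         specs = default_classifier_specs(),
                         out_dir = NULL, k_top = 18, relieff_k = 10,
                         selection_scope = "full",
                         write_all_events = FALSE, ...) {
  validate_cohort_config(config)
  n_tot <- config$n_high_altitude + config$n_low_altitude
  if (config$n_high_altitude < 2 || config$n_low_altitude < 2)
    stop("need at least 2 participants per group to evaluate classifiers")
  rows <- vector("list", n_tot)
  events_list <- vector("list", n_tot)
  labels <- character(n_tot)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n_tot)) {
    rec <- generate_participant(config, i)
    labels[i] <- rec$group_label
    events_list[[i]] <- rec$events
    rows[[i]] <- tryCatch(
      featurize_recording(rec, ...),
      error = function(e) stop("featurize stage failed for participant ",
                               rec$participant_id, ": ", conditionMessage(e)))
    if (!is.null(out_dir) && (write_all_events || i == 1))
      write_events_tsv(rec$events,
                       file.path(out_dir, paste0("events_",
                                                 rec$participant_id, ".tsv")))
  }
  feats <- do.call(rbind, rows)
  periods <- sort(unique(feats$period))
  tables <- lapply(periods, function(pd) {
    tab <- feats[feats$period == pd, feature_names(), drop = FALSE]
    rownames(tab) <- feats$participant[feats$period == pd]
    tab
  })
  names(tables) <- periods
  behavior <- summarize_behavior(events_list, labels)
  report <- evaluate_all(tables, labels, specs, k_top = k_top,
                         relieff_k = relieff_k,
                         selection_scope = selection_scope)
  result <- list(report = report, tables = tables, behavior = behavior,
                 labels = labels, config = config)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

#' Summarize behavioral performance
#'
#' Omission rate (missed responses on Go trials / Go trials) and mean
#' reaction time over responded Go trials, by group and task period.
#'
#' @param events_list List of `gsat_events` data frames (behavior filled).
#' @param groups `"HA"` / `"LA"` label per list element.
#' @return `data.frame` with columns `group`, `period`, `n_go`,
#'   `omission_rate`, `mean_rt`.
#' @export
summarize_behavior <- function(events_list, groups) {
  stopifnot(length(events_list) == length(groups))
  ev <- do.call(rbind, Map(function(e, g) cbind(e, group = g),
                           events_list, groups))
  go <- ev[ev$trial_type == "go", ]
  if (!nrow(go)) stop("no Go trials present")
  if (any(is.na(go$responded)))
    stop("events carry no behavioral responses; synthesize recordings first")
  agg <- do.call(rbind, lapply(split(go, list(go$group, go$period)),
    function(d) data.frame(group = d$group[1], period = d$period[1],
                           n_go = nrow(d),
                           omission_rate = mean(!d$responded),
                           mean_rt = mean(d$rt, na.rm = TRUE),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$group, agg$period), ]
}

# Write CSV/JSON artifacts + MD5 manifest for a pipeline result.
write_run_artifacts <- function(result, out_dir) {
  for (pd in names(result$tables)) {
    tab <- cbind(participant = rownames(result$tables[[pd]]),
                 group = result$labels, result$tables[[pd]])
    utils::write.csv(tab, file.path(out_dir, paste0("features_", pd, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(result$behavior, file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)
  rk <- lapply(result$report$rankings, function(r)
    list(relieff = list(method = "ReliefF",
                        ranking = r$relieff$ranking,
                        scores = as.list(r$relieff$scores)),
         gainratio = list(method = "GainRatio",
                          ranking = r$gainratio$ranking,
                          scores = as.list(r$gainratio$scores))))
  jsonlite::write_json(rk, file.path(out_dir, "rankings.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(selected = result$report$selected,
         metrics = as.data.frame(result$report)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_config_json(result$config, file.path(out_dir, "config.json"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "gsatpipe",
    version = as.character(utils::packageVersion("gsatpipe")),
    seed = result$config$seed,
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.json"))),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
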