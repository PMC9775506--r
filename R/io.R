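#' Write / read a trial-event table as tab-separated text
#'
#' Columns: `onset_s`, `type`, `block`, `period`, `stimulus`, `responded`,
#' `rt_ms` — a BIDS-events-like layout.
#'
#' @param events A `gsat_events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset_s = events$onset, type = events$trial_type,
                    block = events$block, period = events$period,
                    stimulus = events$stimulus,
                    responded = events$responded, rt_ms = events$rt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  ev <- data.frame(onset = d$onset_s, trial_type = d$type, block = d$block,
                   period = d$period, stimulus = d$stimulus,
                   responded = d$responded, rt = d$rt_ms,
                   stringsAsFactors = FALSE)
  class(ev) <- c("gsat_events", "data.frame")
  ev
}

#' Write a continuous recording as columnar text
#'
#' One row per sample: `time_s` then one column per channel (microvolts).
#' A plain, self-describing dump; large at full recording lengths.
#'
#' @param recording A `gsat_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  n <- nrow(recording$samples)
  out <- data.frame(time_s = (seq_len(n) - 1) / recording$sampling_rate)
  for (ch in recording$channel_names) out[[ch]] <- recording$samples[, ch]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an averaged ERP as tidy CSV
#'
#' One row per sample: `participant`, `condition`, `period`, `time_ms`,
#' `amplitude_uv`.
#'
#' @param erp A `gsat_erp` object.
#' @param path Output file path.
#' @param participant Participant identifier written on every row.
#' @return `path`, invisibly.
#' @export
write_erp_csv <- function(erp, path, participant = NA_character_) {
  out <- data.frame(participant = participant,
                    condition = erp$trial_class %||% NA_character_,
                    period = erp$period %||% NA_character_,
                    time_ms = epoch_times(erp),
                    amplitude_uv = erp$x)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an ERSP map as long-format CSV
#'
#' One row per (frame, frequency) cell: `participant`, `condition`,
#' `period`, `time_ms`, `freq_hz`, `db`.
#'
#' @param ersp A `gsat_ersp` object.
#' @param path Output file path.
#' @param participant Participant identifier written on every row.
#' @return `path`, invisibly.
#' @export
write_ersp_csv <- function(ersp, path, participant = NA_character_) {
  out <- data.frame(participant = participant,
                    condition = ersp$trial_class %||% NA_character_,
                    period = ersp$period %||% NA_character_,
                    time_ms = rep(ersp$time_ms, each = length(ersp$freq)),
                    freq_hz = rep(ersp$freq, times = length(ersp$time_ms)),
                    db = as.vector(ersp$values))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pack/unpack numeric arrays so JSON round-trips dim + dimnames losslessly
pack_array <- function(a) {
  if (is.null(dim(a))) {
    list(values = as.numeric(a), names = names(a))
  } else {
    list(values = as.numeric(a), dim = dim(a), dimnames = dimnames(a))
  }
}

unpack_array <- function(p) {
  v <- as.numeric(p$values)
  if (!is.null(p$dim)) {
    array(v, dim = unlist(p$dim), dimnames = lapply(p$dimnames, unlist))
  } else {
    names(v) <- unlist(p$names)
    v
  }
}

#' Serialize / parse a cohort configuration as JSON
#'
#' Field names mirror [cohort_config()] arguments exactly; effect tables are
#' stored with their dimensions and dimnames so that
#' `read_config_json(write_config_json(cfg, f))` reproduces `cfg`.
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @return `path` invisibly (write); a `cohort_config` (read).
#' @export
write_config_json <- function(config, path) {
  validate_cohort_config(config)
  arr_fields <- c("sp_latency_mean", "sp_amplitude_mean", "band_power_offsets",
                  "omission_rate", "sp_latency_type_offset", "band_rms",
                  "rt_mean")
  obj <- unclass(config)
  for (f in arr_fields) obj[[f]] <- pack_array(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arr_fields <- c("sp_latency_mean", "sp_amplitude_mean", "band_power_offsets",
                  "omission_rate", "sp_latency_type_offset", "band_rms",
                  "rt_mean")
  for (f in arr_fields) obj[[f]] <- unpack_array(obj[[f]])
  do.call(cohort_config, obj)
}
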