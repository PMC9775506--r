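#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts one epoch per event over the window `[-200, 1000)` ms relative to
#' stimulus onset (600 samples at 500 Hz). Sample indexing is 0-based with
#' half-open windows: the event onset lands at epoch sample index
#' `round(0.2 * fs)` and an event at t seconds occupies recording samples
#' `round(t*fs) - round(0.2*fs)` through `+ round(1.0*fs) - 1`.
#'
#' @param recording A `gsat_recording`.
#' @param window Length-2 numeric, epoch window in ms relative to onset
#'   (half-open `[start, stop)`).
#' @param channel Analysis channel name.
#' @param filter Optional band-pass edges in Hz (e.g. `c(0.1, 30)`) applied
#'   zero-phase (forward-backward Butterworth, order 2 per pass) to the
#'   continuous signal before epoching, mirroring an offline 0.1-30 Hz
#'   band-pass. Default `NULL` (off): the synthetic generator is already
#'   band-limited and zero-phase filtering is only needed for data that is
#'   not, since the SP latency is a headline feature.
#' @return A `gsat_epochs` object: list with `x` (samples x trials matrix),
#'   `fs`, `t_start_ms`, per-trial `trial_type`, `block`, `period`,
#'   `accepted` (all `TRUE` initially), `baseline_corrected` flag.
#' @export
epoch_signal <- function(recording, window = c(-200, 1000), channel = "CPZ",
                         filter = NULL) {
  stopifnot(inherits(recording, "gsat_recording"), length(window) == 2,
            window[1] < 0, window[2] > 0)
  if (!channel %in% recording$channel_names)
    stop("channel ", channel, " not present in recording")
  fs <- recording$sampling_rate
  sig <- recording$samples[, channel]
  if (!is.null(filter)) {
    bf <- signal::butter(2, filter / (fs / 2), type = "pass")
    sig <- signal::filtfilt(bf, sig)
  }
  ev <- recording$events
  pre <- round(-window[1] / 1000 * fs)
  post <- round(window[2] / 1000 * fs)
  len <- pre + post
  onset_idx <- round(ev$onset * fs)                # 0-based
  start <- onset_idx - pre                          # 0-based, inclusive
  bad <- which(start < 0 | start + len > nrow(recording$samples))
  if (length(bad))
    stop("epoch window out of recording bounds for event(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (onset ", ev$onset[bad[1]], " s)")
  idx <- outer(seq_len(len), start, `+`)            # 1-based rows
  x <- matrix(sig[idx], nrow = len)
  structure(list(x = x, fs = fs, t_start_ms = window[1],
                 trial_type = ev$trial_type, block = ev$block,
                 period = ev$period,
                 responded = ev$responded,
                 accepted = rep(TRUE, ncol(x)),
                 baseline_corrected = FALSE),
            class = "gsat_epochs")
}

#' Epoch sample timestamps
#'
#' @param epochs A `gsat_epochs` (or `gsat_erp`) object.
#' @return Numeric vector of per-sample times in ms relative to stimulus
#'   onset (half-open window; at 500 Hz and a -200 ms start: -200, -198, ...).
#' @export
epoch_times <- function(epochs) {
  n <- if (is.matrix(epochs$x)) nrow(epochs$x) else length(epochs$x)
  epochs$t_start_ms + (seq_len(n) - 1) * 1000 / epochs$fs
}

#' Baseline-correct epochs
#'
#' Subtracts from every sample of each epoch the mean of its pre-stimulus
#' `[-200, 0)` ms interval, so baseline means are exactly zero. Idempotent.
#'
#' @param epochs A `gsat_epochs` object.
#' @param baseline Length-2 numeric, baseline interval in ms (half-open).
#' @return The corrected `gsat_epochs`.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "gsat_epochs"))
  tt <- epoch_times(epochs)
  sel <- tt >= baseline[1] & tt < baseline[2]
  if (!any(sel)) stop("epoch does not span the baseline interval")
  mu <- colMeans(epochs$x[sel, , drop = FALSE])
  epochs$x <- sweep(epochs$x, 2, mu)
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Reject epochs exceeding an absolute-amplitude threshold
#'
#' An epoch is rejected iff its maximum absolute amplitude (after baseline
#' correction) strictly exceeds `threshold` microvolts; an excursion of
#' exactly `threshold` is kept. The per-epoch decision log is attached as
#' attribute `"rejection_log"`.
#'
#' @param epochs A `gsat_epochs` object (baseline-correct first).
#' @param threshold Rejection threshold in microvolts (> 0).
#' @return `gsat_epochs` with updated `accepted` flags.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "gsat_epochs"), threshold > 0)
  peak <- apply(abs(epochs$x), 2, max)
  keep <- peak <= threshold
  epochs$accepted <- epochs$accepted & keep
  log <- data.frame(epoch = seq_along(peak), max_abs_uv = peak,
                    accepted = keep)
  attr(epochs, "rejection_log") <- log
  attr(epochs, "n_rejected") <- sum(!keep)
  epochs
}

# Accepted-epoch selector for a condition; No-Go subtypes pool into "nogo".
condition_index <- function(epochs, trial_class, period = NULL) {
  cls <- ifelse(epochs$trial_type == "go", "go", "nogo")
  sel <- epochs$accepted & cls == trial_class
  if (!is.null(period)) sel <- sel & epochs$period == period
  which(sel)
}

#' Extract the accepted-epoch matrix for one condition
#'
#' @param epochs A `gsat_epochs` object.
#' @param trial_class `"go"` or `"nogo"` (both No-Go subtypes pool).
#' @param period Optional `"a1"`, `"a2"` or `"a3"`.
#' @return Numeric matrix, samples x accepted trials.
#' @export
epoch_matrix <- function(epochs, trial_class, period = NULL) {
  idx <- condition_index(epochs, trial_class, period)
  if (!length(idx))
    stop("no accepted epochs for condition ", trial_class,
         if (!is.null(period)) paste0(" / ", period))
  epochs$x[, idx, drop = FALSE]
}

#' Average epochs into a condition ERP
#'
#' Pointwise arithmetic mean over accepted epochs of the condition; both
#' No-Go subtypes pool into the class `"nogo"`.
#'
#' @inheritParams epoch_matrix
#' @return A `gsat_erp` object: list with `x` (numeric waveform), `fs`,
#'   `t_start_ms`, `n_trials_averaged`, `trial_class`, `period`.
#' @export
average_erp <- function(epochs, trial_class, period = NULL) {
  m <- epoch_matrix(epochs, trial_class, period)
  structure(list(x = rowMeans(m), fs = epochs$fs,
                 t_start_ms = epochs$t_start_ms,
                 n_trials_averaged = ncol(m),
                 trial_class = trial_class, period = period),
            class = "gsat_erp")
}
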