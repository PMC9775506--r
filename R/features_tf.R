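#' Analysis frequency bands
#'
#' The four oscillatory bands of the analysis: theta (4-8 Hz), slow alpha
#' (8-10.5 Hz), fast alpha (10.5-13 Hz) and beta (13-30 Hz). Band intervals
#' are half-open `[lo, hi)` except the 30 Hz beta upper edge, which is
#' inclusive to match the 30 Hz low-pass ceiling; slow and fast alpha
#' therefore never share a frequency bin.
#'
#' @return `data.frame` with columns `name`, `lo`, `hi`.
#' @export
gsat_bands <- function() {
  data.frame(name = c("theta", "slow_alpha", "fast_alpha", "beta"),
             lo = c(4, 8, 10.5, 13),
             hi = c(8, 10.5, 13, 30),
             stringsAsFactors = FALSE)
}

# Hann taper (periodic symmetric cosine window, zero at both ends).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Frame layout for a signal of n samples starting at t_start_ms: frame
# centers sit at integer multiples of the hop relative to stimulus onset
# (t = 0), and frames extending past either epoch edge are dropped, so every
# retained frame is computed from fully valid samples.
frame_grid <- function(n, fs, t_start_ms, window_ms, hop_ms) {
  lw <- round(window_ms * fs / 1000)
  if (lw < 2) stop("STFT window too short at this sampling rate")
  if (lw > n) stop("STFT window longer than the signal")
  hop <- max(1L, round(hop_ms * fs / 1000))
  pre <- round(-t_start_ms * fs / 1000)     # onset sample (0-based)
  off <- (lw - 1) %/% 2                      # center offset within frame
  k_min <- ceiling((off - pre) / hop)
  k_max <- floor((n - lw + off - pre) / hop)
  if (k_max < k_min) stop("no valid STFT frames: window longer than signal")
  k <- k_min:k_max
  start <- pre + k * hop - off               # 0-based frame starts
  center_ms <- t_start_ms + (start + off) * 1000 / fs
  list(lw = lw, start = start, center_ms = center_ms)
}

#' Short-time Fourier transform
#'
#' Hann-tapered, zero-padded FFT of successive frames. Frame centers are
#' aligned to multiples of `hop_ms` relative to stimulus onset (`t = 0` given
#' `t_start_ms`), and frames that would extend past either end of the signal
#' are dropped. Zero-padding to `n_fft = fs / freq_res` samples gives the
#' requested frequency-grid spacing (0.5 Hz by default; set
#' `freq_res = 0.1` for a 0.1 Hz grid).
#'
#' @param x Numeric vector (one epoch or ERP waveform).
#' @param fs Sampling rate in Hz.
#' @param t_start_ms Time of the first sample, ms relative to onset.
#' @param window_ms,hop_ms Frame length and hop in ms.
#' @param freq_res Frequency grid spacing in Hz (via zero-padding).
#' @return List with `coef` (complex `n_fft` x n_frames matrix, two-sided),
#'   `power` (one-sided squared-magnitude matrix, frequencies `freq`),
#'   `freq` (Hz, one-sided), `time_ms` (frame centers), `n_fft`, `window`
#'   (the taper actually applied).
#' @export
stft <- function(x, fs, t_start_ms = -200, window_ms = 250, hop_ms = 20,
                 freq_res = 0.5) {
  g <- frame_grid(length(x), fs, t_start_ms, window_ms, hop_ms)
  n_fft <- max(g$lw, round(fs / freq_res))
  w <- hann_window(g$lw)
  frames <- vapply(g$start, function(s) x[(s + 1):(s + g$lw)] * w,
                   numeric(g$lw))
  frames <- rbind(frames, matrix(0, n_fft - g$lw, length(g$start)))
  coef <- stats::mvfft(frames)
  n_keep <- floor(n_fft / 2) + 1
  pow <- Mod(coef[seq_len(n_keep), , drop = FALSE])^2
  freq <- (seq_len(n_keep) - 1) * fs / n_fft
  list(coef = coef, power = pow, freq = freq, time_ms = g$center_ms,
       n_fft = n_fft, window = w)
}

# Batched per-trial power spectrogram: one mvfft call for all frames of all
# trials. Returns array power[freq <= max_freq, frame, trial].
power_frames <- function(xmat, fs, t_start_ms, window_ms, hop_ms, freq_res,
                         max_freq = 35) {
  g <- frame_grid(nrow(xmat), fs, t_start_ms, window_ms, hop_ms)
  n_fft <- max(g$lw, round(fs / freq_res))
  n_fr <- length(g$start)
  n_tr <- ncol(xmat)
  w <- hann_window(g$lw)
  row_idx <- outer(seq_len(g$lw), g$start, `+`)          # lw x n_fr
  big <- matrix(0, n_fft, n_fr * n_tr)
  for (tr in seq_len(n_tr)) {
    cols <- ((tr - 1) * n_fr + 1):(tr * n_fr)
    big[seq_len(g$lw), cols] <- xmat[row_idx, tr] * w
  }
  coef <- stats::mvfft(big)
  n_keep <- sum((seq_len(floor(n_fft / 2) + 1) - 1) * fs / n_fft <= max_freq)
  pow <- Mod(coef[seq_len(n_keep), , drop = FALSE])^2
  dim(pow) <- c(n_keep, n_fr, n_tr)
  list(power = pow, freq = (seq_len(n_keep) - 1) * fs / n_fft,
       time_ms = g$center_ms)
}

# dB with a power floor guarding log of zero.
power_db <- function(p, floor = 1e-20) 10 * log10(pmax(p, floor))

#' Event-related spectral perturbation (ERSP)
#'
#' Computes a baseline-normalized time-frequency map (dB) for one condition:
#' per-trial Hann STFT power, averaged across trials, converted to log power,
#' minus the per-frequency mean log power of the frames centered in the
#' pre-stimulus baseline. By construction the baseline-interval mean of the
#' map is 0 dB at every frequency.
#'
#' The default averages *power* across trials before taking logs (standard
#' ERSP practice); `average_domain = "log"` instead averages single-trial
#' log power, for comparison with pipelines that do so.
#'
#' @param epochs A `gsat_epochs` object (baseline-corrected, screened).
#' @param trial_class `"go"` or `"nogo"`.
#' @param period Optional period filter (`"a1"`, `"a2"`, `"a3"`).
#' @param window_ms,hop_ms,freq_res STFT parameters, see [stft()].
#' @param baseline Baseline interval in ms (half-open `[lo, hi)`); at least
#'   one frame center must fall inside it.
#' @param average_domain `"power"` or `"log"`.
#' @param max_freq Highest frequency (Hz) retained in the map.
#' @return A `gsat_ersp` object: list with `values` (dB matrix, frequencies x
#'   frames), `freq`, `time_ms`, `baseline`, `n_trials`, `trial_class`,
#'   `period`.
#' @export
compute_ersp <- function(epochs, trial_class, period = NULL,
                         window_ms = 250, hop_ms = 20, freq_res = 0.5,
                         baseline = c(-200, 0), average_domain = "power",
                         max_freq = 35) {
  m <- epoch_matrix(epochs, trial_class, period)
  pf <- power_frames(m, epochs$fs, epochs$t_start_ms, window_ms, hop_ms,
                     freq_res, max_freq)
  average_domain <- match.arg(average_domain, c("power", "log"))
  d <- dim(pf$power)
  if (average_domain == "power") {
    p_bar <- rowMeans(matrix(pf$power, d[1] * d[2], d[3]))
    l <- matrix(power_db(p_bar), d[1], d[2])
  } else {
    l_all <- power_db(pf$power)
    l <- matrix(rowMeans(matrix(l_all, d[1] * d[2], d[3])), d[1], d[2])
  }
  ersp_normalize(l, pf$freq, pf$time_ms, baseline,
                 n_trials = d[3], trial_class = trial_class, period = period)
}

#' Baseline-normalize a log-power spectrogram
#'
#' Subtracts the per-frequency mean baseline log power from every frame.
#' Exposed separately so precomputed spectrograms can be normalized.
#'
#' @param log_power dB matrix, frequencies x frames.
#' @param freq Frequency grid (Hz).
#' @param time_ms Frame-center timestamps (ms).
#' @param baseline Baseline interval `[lo, hi)` in ms.
#' @param n_trials,trial_class,period Metadata carried on the result.
#' @return A `gsat_ersp` object.
#' @export
ersp_normalize <- function(log_power, freq, time_ms, baseline = c(-200, 0),
                           n_trials = NA_integer_, trial_class = NULL,
                           period = NULL) {
  bl <- time_ms >= baseline[1] & time_ms < baseline[2]
  if (!any(bl))
    stop("no STFT frame centered in the baseline interval [",
         baseline[1], ", ", baseline[2], ") ms; shorten the window or hop")
  base <- rowMeans(log_power[, bl, drop = FALSE])
  structure(list(values = log_power - base, freq = freq, time_ms = time_ms,
                 baseline = baseline, n_trials = n_trials,
                 trial_class = trial_class, period = period),
            class = "gsat_ersp")
}

# Frequency-bin selector for a band: [lo, hi), with a 30 Hz upper edge
# treated inclusively (the low-pass ceiling).
band_bins <- function(freq, lo, hi) {
  sel <- freq >= lo & (freq < hi | (hi >= 30 & freq == hi))
  if (!any(sel)) stop("band [", lo, ", ", hi, ") contains no frequency bins")
  which(sel)
}

#' Band features of an ERSP map
#'
#' Over the SP feature window (inclusive `[460, 700]` ms): the mean dB value
#' across all (frame, bin) cells of the band; the maximum over frames of the
#' per-frame band-mean dB; and the frame timestamp of that maximum (earliest
#' frame on ties). The maximum of frame means is never below their mean, so
#' `max_power >= mean_power` always holds.
#'
#' @param ersp A `gsat_ersp` object.
#' @param band Band name (see [gsat_bands()]) or numeric `c(lo, hi)` in Hz.
#' @param window Feature window in ms (inclusive).
#' @return Named list `mean_power` (dB), `max_power` (dB), `time_of_max` (ms).
#' @export
band_features <- function(ersp, band, window = c(460, 700)) {
  if (is.character(band)) {
    bd <- gsat_bands()
    row <- match(band, bd$name)
    if (is.na(row)) stop("unknown band ", band)
    band <- c(bd$lo[row], bd$hi[row])
  }
  bins <- band_bins(ersp$freq, band[1], band[2])
  fr <- which(ersp$time_ms >= window[1] & ersp$time_ms <= window[2])
  if (!length(fr)) stop("feature window not covered by STFT frames")
  sub <- ersp$values[bins, fr, drop = FALSE]
  frame_means <- colMeans(sub)
  imax <- which.max(frame_means)
  list(mean_power = mean(sub), max_power = frame_means[imax],
       time_of_max = ersp$time_ms[fr[imax]])
}

#' The 24 time-frequency features
#'
#' Mean power, max power and time-of-max for each of the four bands, for the
#' Go and No-Go ERSP maps, with stable names (`go_theta_mean`, ...,
#' `nogo_beta_tmax`).
#'
#' @param go_ersp,nogo_ersp `gsat_ersp` objects for the two conditions.
#' @param bands Band table as from [gsat_bands()].
#' @param window Feature window in ms (inclusive).
#' @return Named numeric vector of length 24.
#' @export
tf_features <- function(go_ersp, nogo_ersp, bands = gsat_bands(),
                        window = c(460, 700)) {
  one <- function(ersp, prefix) {
    out <- numeric(0)
    for (bi in seq_len(nrow(bands))) {
      bf <- band_features(ersp, c(bands$lo[bi], bands$hi[bi]), window)
      v <- c(bf$mean_power, bf$max_power, bf$time_of_max)
      names(v) <- paste0(prefix, bands$name[bi], c("_mean", "_max", "_tmax"))
      out <- c(out, v)
    }
    out
  }
  c(one(go_ersp, "go_"), one(nogo_ersp, "nogo_"))
}
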