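#' Canonical feature names
#'
#' The fixed 36-name feature universe: 12 time-domain sustained-potential
#' features and 24 time-frequency (ERSP) features, for the Go and No-Go
#' conditions.
#'
#' @return Character vector of length 36 in canonical column order.
#' @export
feature_names <- function() {
  time_f <- c("latency", "mean", "area", "lat_over_mean", "abs_mean",
              "abs_lat_over_mean")
  tf_f <- as.vector(outer(c("mean", "max", "tmax"),
                          c("theta", "slow_alpha", "fast_alpha", "beta"),
                          function(s, b) paste(b, s, sep = "_")))
  c(paste0("go_", time_f), paste0("nogo_", time_f),
    paste0("go_", tf_f), paste0("nogo_", tf_f))
}

# window sample selector: inclusive [start, stop] ms on the ERP time grid
sp_window_index <- function(erp, window) {
  tt <- epoch_times(erp)
  idx <- which(tt >= window[1] & tt <= window[2])
  if (!length(idx)) stop("SP window contains no samples at this sampling rate")
  idx
}

#' Sustained-potential peak latency
#'
#' Time (ms post-stimulus) at which the maximum sample value of the averaged
#' waveform occurs within the SP window (inclusive `[460, 700]` ms by
#' default). Ties are broken by the earliest time.
#'
#' @param erp A `gsat_erp` object.
#' @param window Length-2 numeric, SP window in ms (inclusive).
#' @return Latency in ms.
#' @export
sp_latency <- function(erp, window = c(460, 700)) {
  idx <- sp_window_index(erp, window)
  tt <- epoch_times(erp)
  tt[idx[which.max(erp$x[idx])]]
}

#' Sustained-potential mean amplitude and total area
#'
#' Mean and plain sum of the waveform samples whose timestamps lie in the
#' inclusive SP window. The area is deliberately reported in
#' microvolt-samples (the unscaled sum), so `area == mean * n_window_samples`
#' holds to machine precision.
#'
#' @inheritParams sp_latency
#' @return Named list `mean_amplitude` (microvolts), `total_area`
#'   (microvolt-samples), `n_samples`.
#' @export
sp_summary <- function(erp, window = c(460, 700)) {
  idx <- sp_window_index(erp, window)
  v <- erp$x[idx]
  list(mean_amplitude = mean(v), total_area = sum(v), n_samples = length(v))
}

#' Latency/amplitude ratio features
#'
#' The latency-over-mean ratio, absolute mean amplitude, and absolute ratio.
#' A zero mean amplitude makes the ratios undefined; they are emitted as `NA`
#' (downstream selection/classification imputes by the column median) rather
#' than crashing the pipeline.
#'
#' @param latency SP latency in ms.
#' @param mean_amplitude SP mean amplitude in microvolts.
#' @return Named list `lat_over_mean`, `abs_mean`, `abs_lat_over_mean`.
#' @export
sp_ratios <- function(latency, mean_amplitude) {
  if (isTRUE(mean_amplitude == 0)) {
    list(lat_over_mean = NA_real_, abs_mean = 0, abs_lat_over_mean = NA_real_)
  } else {
    r <- latency / mean_amplitude
    list(lat_over_mean = r, abs_mean = abs(mean_amplitude),
         abs_lat_over_mean = abs(r))
  }
}

#' The 12 time-domain sustained-potential features
#'
#' Computes, for the Go and No-Go averaged ERPs, the SP peak latency, mean
#' amplitude, total area, latency/mean ratio, absolute mean amplitude and
#' absolute latency/mean ratio over the SP window.
#'
#' @param go_erp,nogo_erp `gsat_erp` objects for the two conditions.
#' @param window SP window in ms (inclusive).
#' @return Named numeric vector of length 12 with stable names
#'   (`go_latency`, `go_mean`, ..., `nogo_abs_lat_over_mean`).
#' @export
time_domain_features <- function(go_erp, nogo_erp, window = c(460, 700)) {
  one <- function(erp, prefix) {
    lat <- sp_latency(erp, window)
    s <- sp_summary(erp, window)
    r <- sp_ratios(lat, s$mean_amplitude)
    v <- c(lat, s$mean_amplitude, s$total_area, r$lat_over_mean,
           r$abs_mean, r$abs_lat_over_mean)
    names(v) <- paste0(prefix, c("latency", "mean", "area", "lat_over_mean",
                                 "abs_mean", "abs_lat_over_mean"))
    v
  }
  c(one(go_erp, "go_"), one(nogo_erp, "nogo_"))
}
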