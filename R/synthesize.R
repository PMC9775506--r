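#' Synthesize a continuous single-channel EEG recording
#'
#' Renders a trial sequence into a continuous recording at the analysis
#' channel ("CPZ") plus simulated behavior. The signal model is additive:
#'
#' * a 1/f background confined below 4 Hz (RMS `noise_sd`),
#' * four band-limited noise components that tile the 4-30 Hz analysis range
#'   (theta 4-8, slow alpha 8-10.5, fast alpha 10.5-13, beta 13-30 Hz) at
#'   baseline RMS `band_rms`, each multiplied post-stimulus (330-830 ms after
#'   every onset) by a gain `10^(dB/20)` so its measured ERSP in the
#'   460-700 ms feature window equals the configured dB offset,
#' * one Gaussian sustained-potential bump per trial (SD `sp_width` ms) whose
#'   peak latency and amplitude are drawn around group x type x period means
#'   with between-subject and trial-to-trial variability.
#'
#' Behavior: each Go trial is responded to with probability
#' `1 - omission_rate[group, period]`; responded trials get a reaction time
#' drawn from `N(rt_mean[period], rt_sd)` truncated at 150 ms. Responses on
#' No-Go trials are not modeled.
#'
#' @param events A `gsat_events` data frame from [generate_trial_sequence()].
#' @param group_label `"HA"` or `"LA"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @param participant_id Identifier stored on the recording.
#' @return An object of class `gsat_recording`: list with `samples` (numeric
#'   matrix, samples x channels, colnames = channel names), `sampling_rate`,
#'   `channel_names`, `events` (with behavior filled in), `group_label`,
#'   `participant_id`.
#' @export
synthesize_recording <- function(events, group_label, config,
                                 seed = config$seed,
                                 participant_id = paste0(group_label, "01")) {
  validate_cohort_config(config)
  stopifnot(nrow(events) > 0, group_label %in% c("HA", "LA"))
  fs <- config$sampling_rate
  n <- ceiling((max(events$onset) + 1.2) * fs)
  bands <- gsat_bands()

  lat_tab <- scale_group_effect(config$sp_latency_mean, config$effect_scale)
  amp_tab <- scale_group_effect(config$sp_amplitude_mean, config$effect_scale)
  off_tab <- scale_group_effect(config$band_power_offsets, config$effect_scale)

  with_seed(seed, {
    # subject-level random effects
    subj_lat <- lat_tab[group_label, ] +
      stats::rnorm(3, 0, config$sp_latency_subject_sd)     # per period
    subj_amp <- amp_tab[group_label, , ] +
      matrix(stats::rnorm(6, 0, config$sp_amplitude_subject_sd), 2, 3)
    subj_off <- off_tab[group_label, , , ] +
      array(stats::rnorm(24, 0, config$band_power_subject_sd), c(4, 2, 3))
    names(subj_lat) <- c("a1", "a2", "a3")
    dimnames(subj_amp) <- list(c("go", "nogo"), c("a1", "a2", "a3"))
    dimnames(subj_off) <- list(bands$name, c("go", "nogo"), c("a1", "a2", "a3"))

    # one white-noise spectrum; the background and the four band components
    # are carved from disjoint frequency bands of it, hence independent
    src <- noise_spectrum(n)
    x <- shaped_noise(n, fs, lo = 0.3, hi = 4, rms = config$noise_sd,
                      one_over_f = TRUE, src = src)

    onset_idx <- round(events$onset * fs)                  # 0-based
    gain_lo <- round(0.330 * fs)
    gain_hi <- round(0.830 * fs)
    per_idx <- match(events$period, c("a1", "a2", "a3"))
    cls <- ifelse(events$trial_type == "go", "go", "nogo")

    for (bi in seq_len(nrow(bands))) {
      comp <- shaped_noise(n, fs, lo = bands$lo[bi], hi = bands$hi[bi],
                           rms = config$band_rms[[bands$name[bi]]],
                           one_over_f = FALSE, src = src)
      if (config$band_rms[[bands$name[bi]]] > 0) {
        for (k in seq_len(nrow(events))) {
          g <- 10 ^ (subj_off[bi, cls[k], per_idx[k]] / 20)
          i0 <- onset_idx[k] + gain_lo + 1L
          i1 <- min(onset_idx[k] + gain_hi, n - 1L) + 1L
          comp[i0:i1] <- comp[i0:i1] * g
        }
      }
      x <- x + comp
    }

    # sustained-potential bumps
    sigma_s <- config$sp_width / 1000
    half <- ceiling(4 * sigma_s * fs)
    for (k in seq_len(nrow(events))) {
      lat <- subj_lat[per_idx[k]] +
        config$sp_latency_type_offset[[cls[k]]] +
        stats::rnorm(1, 0, config$sp_latency_trial_sd)
      amp <- subj_amp[cls[k], per_idx[k]] +
        stats::rnorm(1, 0, config$sp_amplitude_trial_sd)
      center <- onset_idx[k] + round(lat / 1000 * fs)
      idx <- max(0L, center - half):min(n - 1L, center + half)
      t_rel <- (idx - center) / fs
      x[idx + 1L] <- x[idx + 1L] + amp * exp(-t_rel^2 / (2 * sigma_s^2))
    }

    # behavior
    ev <- events
    is_go <- ev$trial_type == "go"
    p_omit <- config$omission_rate[group_label, ][per_idx]
    ev$responded <- FALSE
    ev$responded[is_go] <- stats::runif(sum(is_go)) >= p_omit[is_go]
    ev$rt <- NA_real_
    n_resp <- sum(ev$responded)
    rts <- stats::rnorm(n_resp, config$rt_mean[ev$period[ev$responded]],
                        config$rt_sd)
    ev$rt[ev$responded] <- pmax(rts, 150)

    samples <- matrix(x, ncol = 1, dimnames = list(NULL, "CPZ"))
    structure(list(samples = samples,
                   sampling_rate = fs,
                   channel_names = "CPZ",
                   events = ev,
                   group_label = group_label,
                   participant_id = participant_id),
              class = "gsat_recording")
  })
}

# Gaussian noise with power confined to [lo, hi) Hz, optionally 1/f-shaped,
# scaled to a target RMS. FFT-domain construction keeps components exactly
# band-limited so the four oscillatory bands never leak into each other.
# White-noise spectrum of (composite) length >= n, shared by all components
# of one recording: disjoint frequency bands of a Gaussian white process are
# independent, so carving each component from its own band of one spectrum
# is statistically identical to five independent draws, at a fifth the cost.
noise_spectrum <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))      # composite length keeps the FFT fast
  list(spec = stats::fft(stats::rnorm(m)), m = m)
}

shaped_noise <- function(n, fs, lo, hi, rms, one_over_f = FALSE, src = NULL) {
  if (rms <= 0) return(numeric(n))
  if (is.null(src)) src <- noise_spectrum(n)
  m <- src$m
  freq <- (seq_len(m) - 1) * fs / m
  freq <- pmin(freq, fs - freq)                  # two-sided |f|
  mask <- freq >= lo & freq < hi
  shape <- as.numeric(mask)
  if (one_over_f) shape[mask] <- 1 / sqrt(pmax(freq[mask], lo))
  x <- Re(stats::fft(src$spec * shape, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (rms / s)
}

#' Reduced-scale and strong-effect study configurations
#'
#' `reduced_config()` is the calibrated-default cohort at a computationally
#' light scale: one block per period (3 blocks of 74 trials, 66 Go + 8
#' No-Go — one ninth of the full 9 x 222 design). So that the miniature
#' remains a faithful model of the full-scale study at the *averaged-ERP*
#' level, the stochastic per-trial signal components (background noise, band
#' RMS, trial-to-trial SP latency/amplitude jitter) are divided by
#' `sqrt(9) = 3`: averaging 66 trials then yields the same ERP
#' signal-to-noise as averaging 594 trials of full-amplitude noise, and the
#' measured feature distributions match the emulated design. Group effect
#' sizes and between-subject variability are untouched.
#'
#' `strong_effect_config()` additionally triples the HA-LA separations of
#' the SP latency/amplitude and band-offset means (`effect_scale = 3`): the
#' positive-control condition under which the pipeline is expected to
#' classify nearly perfectly.
#'
#' @param n_per_group Participants per group.
#' @param seed Master seed.
#' @param trial_scale Trial-count reduction factor relative to the full
#'   design (9 = one block instead of three per period and a third of the
#'   trials per block).
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
reduced_config <- function(n_per_group = 12, seed = 1L, trial_scale = 9, ...) {
  s <- sqrt(trial_scale)
  cohort_config(n_high_altitude = n_per_group, n_low_altitude = n_per_group,
                n_blocks = 3, trials_per_block = 74, n_go_per_block = 66,
                n_nogo_per_block = 8,
                noise_sd = 10 / s,
                band_rms = c(theta = 5, slow_alpha = 4, fast_alpha = 4,
                             beta = 3) / s,
                sp_latency_trial_sd = 50 / s,
                sp_amplitude_trial_sd = 2 / s,
                seed = seed, ...)
}

#' @rdname reduced_config
#' @export
strong_effect_config <- function(n_per_group = 10, seed = 1L, ...) {
  reduced_config(n_per_group = n_per_group, seed = seed, effect_scale = 3, ...)
}

#' Generate a full two-group synthetic cohort
#'
#' Generates `n_high_altitude + n_low_altitude` recordings, each with its own
#' trial sequence and a per-participant sub-seed derived deterministically
#' from `config$seed` (no seed collisions, fully reproducible).
#'
#' Note that a default-scale cohort (67 participants x ~70 min at 500 Hz) is
#' around 1 GB as a list; [run_pipeline()] instead streams participants one
#' at a time and never holds the whole cohort.
#'
#' @param config A [cohort_config()].
#' @return List of `gsat_recording`, HA participants first.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n_tot <- config$n_high_altitude + config$n_low_altitude
  lapply(seq_len(n_tot), function(i) generate_participant(config, i))
}

# Generate participant i (HA first) of a cohort: events + recording.
generate_participant <- function(config, i) {
  grp <- if (i <= config$n_high_altitude) "HA" else "LA"
  idx <- if (grp == "HA") i else i - config$n_high_altitude
  id <- sprintf("%s%02d", grp, idx)
  sd_ev <- participant_seed(config$seed, 2L * i)
  sd_rec <- participant_seed(config$seed, 2L * i + 1L)
  ev <- generate_trial_sequence(config, seed = sd_ev)
  synthesize_recording(ev, grp, config, seed = sd_rec, participant_id = id)
}
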