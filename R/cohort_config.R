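#' Default sustained-potential latency means (ms)
#'
#' Group-by-period means of the SP peak latency at the analysis channel,
#' pooled over stimulus type. The high-altitude (HA) group peaks earlier than
#' the low-altitude (LA) group in the early (a1) and late (a3) task periods,
#' with a smaller difference mid-task (a2).
#'
#' @return A 2 x 3 numeric matrix (rows `HA`, `LA`; columns `a1`, `a2`, `a3`).
#' @export
default_sp_latency <- function() {
  m <- matrix(c(531.51, 538.57, 528.14,
                579.63, 560.97, 565.97),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("HA", "LA"), c("a1", "a2", "a3")))
  m
}

#' Default sustained-potential amplitude means (microvolts)
#'
#' Group x stimulus-type x period means of the SP amplitude. No-Go trials
#' elicit a substantially larger SP than Go trials; the LA group runs slightly
#' higher than HA in both conditions.
#'
#' @return A numeric array with dim `c(2, 2, 3)` and dimnames
#'   `list(c("HA","LA"), c("go","nogo"), c("a1","a2","a3"))`.
#' @export
default_sp_amplitude <- function() {
  a <- array(NA_real_, dim = c(2, 2, 3),
             dimnames = list(c("HA", "LA"), c("go", "nogo"),
                             c("a1", "a2", "a3")))
  a["HA", "go", ]   <- c(5.02, 5.60, 5.84)
  a["LA", "go", ]   <- c(6.89, 6.56, 6.69)
  a["HA", "nogo", ] <- c(11.39, 12.52, 13.62)
  a["LA", "nogo", ] <- c(13.55, 14.80, 14.54)
  a
}

#' Default post-stimulus band-power offsets (dB)
#'
#' Group x band x stimulus-type x period event-related spectral perturbation
#' offsets relative to the pre-stimulus baseline, in the 460-700 ms window.
#' Positive values mean post-stimulus band power above baseline. The HA group
#' shows stronger theta (notably late in the task) and less alpha/beta
#' desynchronization than LA.
#'
#' @return A numeric array with dim `c(2, 4, 2, 3)` and dimnames
#'   `(group, band, type, period)`.
#' @export
default_band_offsets <- function() {
  b <- array(NA_real_, dim = c(2, 4, 2, 3),
             dimnames = list(c("HA", "LA"),
                             c("theta", "slow_alpha", "fast_alpha", "beta"),
                             c("go", "nogo"),
                             c("a1", "a2", "a3")))
  b["HA", "theta", "go", ]        <- c(0.84, 1.07, 1.44)
  b["LA", "theta", "go", ]        <- c(0.84, 0.74, 0.88)
  b["HA", "theta", "nogo", ]      <- c(-0.01, -0.03, 0.13)
  b["LA", "theta", "nogo", ]      <- c(-0.19, -0.27, -0.43)
  b["HA", "slow_alpha", "go", ]   <- c(-0.10, -0.13, -0.17)
  b["LA", "slow_alpha", "go", ]   <- c(-0.14, -0.17, -0.20)
  b["HA", "slow_alpha", "nogo", ] <- c(-0.01, -0.02, -0.02)
  b["LA", "slow_alpha", "nogo", ] <- c(-0.18, -0.27, -0.42)
  b["HA", "fast_alpha", "go", ]   <- c(-0.09, -0.12, -0.15)
  b["LA", "fast_alpha", "go", ]   <- c(-0.17, -0.18, -0.18)
  b["HA", "fast_alpha", "nogo", ] <- c(-0.14, -0.03, -0.11)
  b["LA", "fast_alpha", "nogo", ] <- c(-0.28, -0.31, -0.37)
  b["HA", "beta", "go", ]         <- c(-0.04, -0.03, -0.05)
  b["LA", "beta", "go", ]         <- c(-0.11, -0.10, -0.08)
  b["HA", "beta", "nogo", ]       <- c(-0.07, -0.05, -0.09)
  b["LA", "beta", "nogo", ]       <- c(-0.17, -0.19, -0.16)
  b
}

#' Default Go-trial omission rates
#'
#' Group x period probabilities of failing to respond on a Go trial. Chosen to
#' be simultaneously consistent with the group means (HA 1.33%, LA 3.98%), the
#' a1 values (HA 1.54%, LA 4.21%) and the pooled period means (a1 2.82%,
#' a2 2.20%) of the study population the generator emulates.
#'
#' @return A 2 x 3 numeric matrix (rows `HA`, `LA`; columns `a1`, `a2`, `a3`).
#' @export
default_omission_rates <- function() {
  matrix(c(0.0154, 0.0120, 0.0125,
           0.0421, 0.0329, 0.0444),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("HA", "LA"), c("a1", "a2", "a3")))
}

#' Cohort configuration for the synthetic Go/No-Go EEG generator
#'
#' Bundles every tunable of the synthetic two-group cohort: task structure
#' (blocks, trial counts, timing), the sustained-potential (SP) signal model
#' (latency/amplitude means and variabilities, bump width), the oscillatory
#' model (band-power ERSP offsets and baseline band amplitudes), background
#' noise, and the behavioral model (omission rates, reaction times).
#'
#' Defaults emulate a 35 HA + 32 LA study of 9 blocks x 222 trials
#' (198 Go + 24 No-Go), 600 ms stimuli with a 1500 ms inter-stimulus interval,
#' sampled at 500 Hz at a single centro-parietal channel ("CPZ").
#'
#' @param n_high_altitude,n_low_altitude Participants per group.
#' @param sampling_rate Sampling rate in Hz. Must exceed twice the highest
#'   analysis band edge (30 Hz).
#' @param n_blocks Number of task blocks; must be divisible by 3 so blocks map
#'   onto the three task periods a1/a2/a3.
#' @param trials_per_block,n_go_per_block,n_nogo_per_block Trial counts; Go
#'   plus No-Go must equal the total.
#' @param n_repeat_nogo_per_block How many of the No-Go trials per block are
#'   repeat No-Go (stimulus identical to the immediately preceding congruent
#'   trial); the rest are incongruent No-Go. Default: an even split.
#' @param stimulus_duration,isi Stimulus duration and inter-stimulus interval
#'   (ms). Onset spacing is their sum (2100 ms by default).
#' @param sp_latency_mean 2 x 3 matrix of SP peak-latency means (ms), group x
#'   period, pooled over stimulus type; see [default_sp_latency()].
#' @param sp_latency_type_offset Named vector `c(go=, nogo=)` of latency
#'   offsets (ms) applied around the pooled mean (Go peaks earlier).
#' @param sp_latency_subject_sd,sp_latency_trial_sd Between-subject and
#'   trial-to-trial SD of the SP latency (ms).
#' @param sp_amplitude_mean group x type x period array of SP amplitudes
#'   (microvolts); see [default_sp_amplitude()].
#' @param sp_amplitude_subject_sd,sp_amplitude_trial_sd Between-subject and
#'   trial-to-trial SD of the SP amplitude (microvolts).
#' @param sp_width Gaussian SP bump standard deviation (ms).
#' @param band_power_offsets group x band x type x period array of ERSP
#'   offsets in dB; see [default_band_offsets()].
#' @param band_power_subject_sd Between-subject SD of each band offset (dB).
#' @param band_rms Named vector of baseline RMS amplitudes (microvolts) of the
#'   four oscillatory components (theta, slow_alpha, fast_alpha, beta).
#' @param noise_sd RMS amplitude (microvolts) of the 1/f background confined
#'   below 4 Hz (the oscillatory components tile 4-30 Hz).
#' @param omission_rate 2 x 3 matrix of Go omission probabilities, group x
#'   period; see [default_omission_rates()].
#' @param rt_mean,rt_sd Reaction-time mean per period (named vector, ms) and
#'   common SD (ms) for responded Go trials.
#' @param effect_scale Multiplier applied to the HA-LA separation of the SP
#'   latency/amplitude and band-offset means (1 = calibrated defaults;
#'   larger values produce more separable groups for power studies).
#' @param seed Integer master seed; per-participant sub-seeds are derived
#'   deterministically from it.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_high_altitude = 2, n_low_altitude = 2, n_blocks = 3)
#' cfg$trials_per_block
#' @export
cohort_config <- function(n_high_altitude = 35,
                          n_low_altitude = 32,
                          sampling_rate = 500,
                          n_blocks = 9,
                          trials_per_block = 222,
                          n_go_per_block = 198,
                          n_nogo_per_block = 24,
                          n_repeat_nogo_per_block = n_nogo_per_block %/% 2,
                          stimulus_duration = 600,
                          isi = 1500,
                          sp_latency_mean = default_sp_latency(),
                          sp_latency_type_offset = c(go = -33, nogo = 33),
                          sp_latency_subject_sd = 45,
                          sp_latency_trial_sd = 50,
                          sp_amplitude_mean = default_sp_amplitude(),
                          sp_amplitude_subject_sd = 3,
                          sp_amplitude_trial_sd = 2,
                          sp_width = 60,
                          band_power_offsets = default_band_offsets(),
                          band_power_subject_sd = 0.5,
                          band_rms = c(theta = 5, slow_alpha = 4,
                                       fast_alpha = 4, beta = 3),
                          noise_sd = 10,
                          omission_rate = default_omission_rates(),
                          rt_mean = c(a1 = 461.58, a2 = 431.49, a3 = 426.53),
                          rt_sd = 85,
                          effect_scale = 1,
                          seed = 1L) {
  cfg <- list(n_high_altitude = as.integer(n_high_altitude),
              n_low_altitude = as.integer(n_low_altitude),
              sampling_rate = sampling_rate,
              n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              n_go_per_block = as.integer(n_go_per_block),
              n_nogo_per_block = as.integer(n_nogo_per_block),
              n_repeat_nogo_per_block = as.integer(n_repeat_nogo_per_block),
              stimulus_duration = stimulus_duration,
              isi = isi,
              sp_latency_mean = sp_latency_mean,
              sp_latency_type_offset = sp_latency_type_offset,
              sp_latency_subject_sd = sp_latency_subject_sd,
              sp_latency_trial_sd = sp_latency_trial_sd,
              sp_amplitude_mean = sp_amplitude_mean,
              sp_amplitude_subject_sd = sp_amplitude_subject_sd,
              sp_amplitude_trial_sd = sp_amplitude_trial_sd,
              sp_width = sp_width,
              band_power_offsets = band_power_offsets,
              band_power_subject_sd = band_power_subject_sd,
              band_rms = band_rms,
              noise_sd = noise_sd,
              omission_rate = omission_rate,
              rt_mean = rt_mean,
              rt_sd = rt_sd,
              effect_scale = effect_scale,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants: trial counts add up, rates lie in
#' \[0, 1\], the sampling rate supports the 30 Hz band ceiling, blocks divide
#' into three periods, and effect tables have the expected shapes.
#'
#' @param cfg A `cohort_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_go_per_block + cfg$n_nogo_per_block != cfg$trials_per_block)
    stop("n_go_per_block + n_nogo_per_block must equal trials_per_block")
  if (cfg$n_repeat_nogo_per_block < 0 ||
      cfg$n_repeat_nogo_per_block > cfg$n_nogo_per_block)
    stop("n_repeat_nogo_per_block must lie in [0, n_nogo_per_block]")
  if (cfg$sampling_rate <= 2 * 30)
    stop("sampling_rate must exceed twice the highest band edge (30 Hz)")
  if (cfg$n_blocks %% 3 != 0)
    stop("n_blocks must be divisible by 3 (three task periods)")
  if (any(cfg$omission_rate < 0) || any(cfg$omission_rate > 1))
    stop("omission rates must lie in [0, 1]")
  if (cfg$n_high_altitude < 0 || cfg$n_low_altitude < 0)
    stop("group sizes must be non-negative")
  stopifnot(identical(dim(cfg$sp_latency_mean), c(2L, 3L)),
            identical(dim(cfg$sp_amplitude_mean), c(2L, 2L, 3L)),
            identical(dim(cfg$band_power_offsets), c(2L, 4L, 2L, 3L)),
            identical(dim(cfg$omission_rate), c(2L, 3L)),
            length(cfg$band_rms) == 4L,
            length(cfg$rt_mean) == 3L)
  if (cfg$effect_scale < 0) stop("effect_scale must be non-negative")
  invisible(cfg)
}

#' Map block indices to task periods
#'
#' Blocks are split into three equal consecutive periods a1 (early), a2
#' (middle), a3 (late): with 9 blocks, blocks 1-3 are a1, 4-6 a2, 7-9 a3.
#'
#' @param block Integer vector of block indices (1-based).
#' @param n_blocks Total number of blocks (divisible by 3).
#' @return Character vector of `"a1"`, `"a2"`, `"a3"`.
#' @export
block_period <- function(block, n_blocks = 9L) {
  if (n_blocks %% 3 != 0) stop("n_blocks must be divisible by 3")
  paste0("a", ceiling(3 * block / n_blocks))
}

# Apply effect_scale to a group-indexed table: pull each group's cell toward /
# away from the unweighted HA-LA midpoint. dim 1 must be group.
scale_group_effect <- function(tab, effect_scale) {
  if (effect_scale == 1) return(tab)
  mid <- (slice_group(tab, 1L) + slice_group(tab, 2L)) / 2
  out <- tab
  assign_group(out, 1L) <- mid + effect_scale * (slice_group(tab, 1L) - mid)
  assign_group(out, 2L) <- mid + effect_scale * (slice_group(tab, 2L) - mid)
  out
}

slice_group <- function(tab, g) {
  d <- dim(tab)
  if (length(d) == 2) tab[g, , drop = TRUE]
  else if (length(d) == 3) tab[g, , , drop = TRUE]
  else tab[g, , , , drop = TRUE]
}

`assign_group<-` <- function(tab, g, value) {
  d <- dim(tab)
  if (length(d) == 2) tab[g, ] <- value
  else if (length(d) == 3) tab[g, , ] <- value
  else tab[g, , , ] <- value
  tab
}

# Deterministic per-participant sub-seed from the master seed (kept < 2^31).
participant_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + index * 7919) %% 2147483647)
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
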