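test_that("STFT localizes a pure 6 Hz tone in the theta band in every frame", {
  fs <- 500
  tt <- seq(-0.2, 1, by = 1 / fs)[1:600]
  x <- sin(2 * pi * 6 * tt)
  s <- stft(x, fs)
  # oracle: direct DFT of each tapered frame
  for (fr in c(1, 10, ncol(s$power))) {
    peak_bin <- which.max(s$power[, fr])
    expect_gte(s$freq[peak_bin], 4)
    expect_lt(s$freq[peak_bin], 8)
  }
  # independent direct-DFT oracle on one frame
  g <- gsatpipe:::frame_grid(600, fs, -200, 250, 20)
  fr1 <- x[(g$start[5] + 1):(g$start[5] + g$lw)] * s$window
  n_fft <- s$n_fft
  k <- 0:(n_fft - 1)
  direct <- vapply(k[1:61], function(kk)
    abs(sum(fr1 * exp(-2i * pi * kk * (seq_along(fr1) - 1) / n_fft)))^2, 0)
  expect_equal(s$power[1:61, 5], direct, tolerance = 1e-8)
})

test_that("STFT frames satisfy Parseval's identity", {
  set.seed(3)
  x <- rnorm(600)
  s <- stft(x, 500)
  g <- gsatpipe:::frame_grid(600, 500, -200, 250, 20)
  for (fr in c(1, 7, length(g$start))) {
    tap <- x[(g$start[fr] + 1):(g$start[fr] + g$lw)] * s$window
    lhs <- sum(tap^2)
    rhs <- sum(Mod(s$coef[, fr])^2) / s$n_fft
    expect_equal(lhs, rhs, tolerance = 1e-6 * lhs)
  }
})

test_that("zero signal gives zero power with a guarded dB floor", {
  s <- stft(rep(0, 600), 500)
  expect_true(all(s$power == 0))
  expect_equal(unique(as.vector(gsatpipe:::power_db(s$power))), -200)
})

test_that("frame centers align to hop multiples and drop edge-crossing frames", {
  s <- stft(rnorm(600), 500)
  expect_true(all(s$time_ms %% 20 == 0))
  expect_equal(min(s$time_ms), -60)    # earliest full 250 ms frame
  expect_equal(max(s$time_ms), 860)
  expect_true(all(c(460, 600, 700) %in% s$time_ms))
  expect_error(stft(rnorm(50), 500), "longer than the signal")
})

test_that("ERSP of a stationary signal is 0 dB", {
  fs <- 500
  tt <- (seq_len(600) - 1) / fs - 0.2
  # hop-periodic signal: every STFT frame sees identical samples, so the
  # spectrogram is frame-constant and baseline subtraction cancels exactly
  x <- sin(2 * pi * 50 * tt) + 0.3 * sin(2 * pi * 100 * tt + 0.4)
  er <- compute_ersp(make_epochs(cbind(x, x, x)), "go", "a1")
  # exact up to floating-point cancellation at deep spectral-leakage nulls
  expect_lt(max(abs(er$values)), 1e-6)
  # baseline-interval mean is 0 dB by construction
  bl <- er$time_ms >= -200 & er$time_ms < 0
  expect_lt(max(abs(rowMeans(er$values[, bl, drop = FALSE]))), 1e-9)
  # statistically stationary noise, many trials: near 0 dB post-stimulus
  set.seed(14)
  xm <- matrix(rnorm(600 * 200), 600, 200)
  er2 <- compute_ersp(make_epochs(xm), "go", "a1")
  post <- er2$time_ms >= 460 & er2$time_ms <= 700
  expect_lt(abs(mean(er2$values[, post])), 0.5)
})

test_that("a 10x post-stimulus power step reads as +10 dB", {
  fs <- 500
  tt <- (seq_len(600) - 1) / fs - 0.2
  gain <- ifelse(tt >= 0.2, sqrt(10), 1)   # power x10 from 200 ms on
  x <- sin(2 * pi * 6 * tt) * gain
  er <- compute_ersp(make_epochs(cbind(x)), "go", "a1")
  # frames fully inside the gained region, at the tone's bin
  bin <- which.min(abs(er$freq - 6))
  late <- er$time_ms >= 460 & er$time_ms <= 700
  expect_equal(mean(er$values[bin, late]), 10, tolerance = 0.2)
})

test_that("ERSP is invariant under amplitude scaling of the whole signal", {
  set.seed(11)
  x <- matrix(rnorm(600 * 4), 600, 4)
  e1 <- compute_ersp(make_epochs(x), "go", "a1")
  e2 <- compute_ersp(make_epochs(5 * x), "go", "a1")
  expect_equal(e1$values, e2$values, tolerance = 1e-9)
})

test_that("band bins partition 8-13 Hz between slow and fast alpha", {
  freq <- seq(0, 35, by = 0.5)
  slow <- gsatpipe:::band_bins(freq, 8, 10.5)
  fast <- gsatpipe:::band_bins(freq, 10.5, 13)
  expect_length(intersect(slow, fast), 0)
  both <- sort(c(slow, fast))
  expect_equal(freq[both], freq[freq >= 8 & freq < 13])
  # beta includes its 30 Hz upper edge
  beta <- gsatpipe:::band_bins(freq, 13, 30)
  expect_true(30 %in% freq[beta])
  expect_error(gsatpipe:::band_bins(c(0, 50), 4, 8), "no frequency bins")
})

test_that("band features obey their definitions and order statistics", {
  # constant map: mean == max, earliest frame of the window wins ties
  freq <- seq(0, 35, by = 0.5)
  time_ms <- seq(-60, 860, by = 20)
  vals <- matrix(2.5, length(freq), length(time_ms))
  er <- structure(list(values = vals, freq = freq, time_ms = time_ms,
                       baseline = c(-200, 0)), class = "gsat_ersp")
  bf <- band_features(er, "theta")
  expect_equal(unlist(bf), c(mean_power = 2.5, max_power = 2.5,
                             time_of_max = 460))
  # single-frame spike at 600 ms
  vals2 <- vals; vals2[, time_ms == 600] <- 9
  er2 <- structure(list(values = vals2, freq = freq, time_ms = time_ms,
                        baseline = c(-200, 0)), class = "gsat_ersp")
  expect_equal(band_features(er2, "beta")$time_of_max, 600)
  # random map: max of frame means >= grand mean, always
  set.seed(2)
  vals3 <- matrix(rnorm(length(freq) * length(time_ms)), length(freq))
  er3 <- structure(list(values = vals3, freq = freq, time_ms = time_ms,
                        baseline = c(-200, 0)), class = "gsat_ersp")
  for (b in gsat_bands()$name) {
    bf3 <- band_features(er3, b)
    expect_gte(bf3$max_power, bf3$mean_power)
    expect_true(bf3$time_of_max >= 460 && bf3$time_of_max <= 700)
  }
})

test_that("the time-frequency vector has 24 stable names and condition symmetry", {
  set.seed(4)
  x <- matrix(rnorm(600 * 6), 600, 6)
  ep <- make_epochs(x)
  er <- compute_ersp(ep, "go", "a1")
  v <- tf_features(er, er)
  expect_length(v, 24)
  expect_true(all(grepl("^(go|nogo)_(theta|slow_alpha|fast_alpha|beta)_(mean|max|tmax)$",
                        names(v))))
  expect_equal(unname(v[1:12]), unname(v[13:24]))
})

test_that("trial-averaging order power-then-log differs from log-then-average as documented", {
  set.seed(9)
  x <- matrix(rnorm(600 * 8, sd = rep(c(1, 3), each = 600 * 4)), 600, 8)
  ep <- make_epochs(x)
  e_pow <- compute_ersp(ep, "go", "a1", average_domain = "power")
  e_log <- compute_ersp(ep, "go", "a1", average_domain = "log")
  expect_false(isTRUE(all.equal(e_pow$values, e_log$values)))
})

test_that("a configured theta ERSP offset is recovered from synthesized trials", {
  offs <- default_band_offsets() * 0
  offs["HA", "theta", "go", "a1"] <- 2
  cfg <- cohort_config(n_high_altitude = 1, n_low_altitude = 1, n_blocks = 3,
                       trials_per_block = 120, n_go_per_block = 116,
                       n_nogo_per_block = 4, noise_sd = 0,
                       sp_amplitude_mean = default_sp_amplitude() * 0,
                       sp_amplitude_subject_sd = 0, sp_amplitude_trial_sd = 0,
                       band_power_subject_sd = 0, band_power_offsets = offs,
                       seed = 5)
  rec <- synthesize_recording(generate_trial_sequence(cfg, 1), "HA", cfg, 9)
  ep <- baseline_correct(epoch_signal(rec))
  er <- compute_ersp(ep, "go", "a1")
  got <- band_features(er, "theta")$mean_power
  # leakage from un-gained neighbor bands and finite trials attenuate the
  # configured +2 dB; it must still be recovered as a clearly positive
  # theta-specific elevation
  expect_gt(got, 1.0)
  expect_lt(abs(band_features(er, "beta")$mean_power), 1.0)
})
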