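# Small configurations and hand-built objects shared across tests.

tiny_config <- function(seed = 1L, ...) {
  cohort_config(n_high_altitude = 2, n_low_altitude = 2, n_blocks = 3,
                trials_per_block = 20, n_go_per_block = 16,
                n_nogo_per_block = 4, seed = seed, ...)
}

# config with all stochastic components switched off: the recording is the
# deterministic SP template
noiseless_config <- function(...) {
  tiny_config(noise_sd = 0,
              band_rms = c(theta = 0, slow_alpha = 0, fast_alpha = 0, beta = 0),
              sp_latency_subject_sd = 0, sp_latency_trial_sd = 0,
              sp_amplitude_subject_sd = 0, sp_amplitude_trial_sd = 0, ...)
}

# build a gsat_erp directly from a waveform sampled on the standard epoch
# grid ([-200, 1000) ms at 500 Hz unless overridden)
make_erp <- function(x, fs = 500, t_start_ms = -200) {
  structure(list(x = x, fs = fs, t_start_ms = t_start_ms,
                 n_trials_averaged = 1L, trial_class = "go", period = "a1"),
            class = "gsat_erp")
}

# ERP whose value is given by f(t_ms) on the standard grid
erp_from_fun <- function(f, fs = 500, t_start_ms = -200, t_stop_ms = 1000) {
  tt <- seq(t_start_ms, t_stop_ms - 1000 / fs, by = 1000 / fs)
  make_erp(f(tt), fs = fs, t_start_ms = t_start_ms)
}

# build a gsat_epochs object from a samples x trials matrix
make_epochs <- function(x, fs = 500, t_start_ms = -200,
                        trial_type = rep("go", ncol(x)),
                        period = rep("a1", ncol(x))) {
  structure(list(x = x, fs = fs, t_start_ms = t_start_ms,
                 trial_type = trial_type, block = rep(1L, ncol(x)),
                 period = period, responded = rep(TRUE, ncol(x)),
                 accepted = rep(TRUE, ncol(x)), baseline_corrected = FALSE),
            class = "gsat_epochs")
}

# independent brute-force ReliefF (all anchors, Manhattan diff normalized by
# feature range) used as the oracle for the fast implementation
brute_relieff <- function(x, labels, k) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(col) {
    r <- max(col) - min(col)
    if (r == 0) 1 else r
  })
  xn <- sweep(x, 2, rng, "/")
  w <- numeric(p)
  for (i in seq_len(n)) {
    di <- colSums(abs(t(xn) - xn[i, ]))
    hits <- setdiff(which(labels == labels[i]), i)
    misses <- which(labels != labels[i])
    hits <- hits[order(di[hits], hits)][1:k]
    misses <- misses[order(di[misses], misses)][1:k]
    for (j in seq_len(p)) {
      w[j] <- w[j] + mean(abs(xn[misses, j] - xn[i, j])) -
        mean(abs(xn[hits, j] - xn[i, j]))
    }
  }
  w / n
}

# entropy/gain-ratio oracle via explicit enumeration of all thresholds
brute_gainratio <- function(col, labels) {
  ent <- function(y) {
    p <- table(y) / length(y); p <- p[p > 0]
    -sum(p * log2(p))
  }
  vals <- sort(unique(col))
  if (length(vals) < 2) return(0)
  thr <- (vals[-1] + vals[-length(vals)]) / 2
  n <- length(col)
  best <- -Inf; best_nl <- NA
  for (t in thr) {
    left <- col <= t
    g <- ent(labels) - mean(left) * ent(labels[left]) -
      mean(!left) * ent(labels[!left])
    if (g > best + 1e-12) { best <- g; best_nl <- sum(left) }
  }
  pl <- best_nl / n
  si <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
  if (si == 0) 0 else best / si
}
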