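#' Generate a Go/No-Go trial sequence
#'
#' Builds the stimulus schedule for one participant: `n_blocks` blocks of
#' `trials_per_block` trials each, with the configured Go / No-Go split.
#' No-Go trials are subtyped into incongruent No-Go (word and font color
#' disagree) and repeat No-Go (a congruent stimulus identical to the
#' immediately preceding congruent Go trial). Onsets are spaced by
#' `stimulus_duration + isi` (2100 ms by default) with a 1 s lead-in so the
#' pre-stimulus epoch window of the first trial is in-bounds.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the sequence is deterministic given it.
#' @return A `data.frame` of class `gsat_events` with columns `onset` (s),
#'   `trial_type` (`go`, `nogo_incongruent`, `nogo_repeat`), `block`,
#'   `period`, `stimulus` (word identity 1-6), `responded` (logical, `NA`
#'   until behavior is simulated) and `rt` (ms, `NA` for non-responses).
#' @examples
#' ev <- generate_trial_sequence(cohort_config(n_blocks = 3,
#'   trials_per_block = 10, n_go_per_block = 8, n_nogo_per_block = 2), seed = 1)
#' table(ev$trial_type)
#' @export
generate_trial_sequence <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  n_words <- 6L
  with_seed(seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      lay <- place_nogo_trials(config$trials_per_block,
                               config$n_nogo_per_block,
                               config$n_repeat_nogo_per_block)
      n <- config$trials_per_block
      stimulus <- sample.int(n_words, n, replace = TRUE)
      # repeat No-Go copies the identity of its (congruent) predecessor
      for (p in which(lay == "nogo_repeat")) stimulus[p] <- stimulus[p - 1L]
      data.frame(trial_type = lay, block = b, stimulus = stimulus,
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, blocks)
    ev$period <- block_period(ev$block, config$n_blocks)
    spacing <- (config$stimulus_duration + config$isi) / 1000
    ev$onset <- 1 + (seq_len(nrow(ev)) - 1L) * spacing
    ev$responded <- NA
    ev$rt <- NA_real_
    ev <- ev[, c("onset", "trial_type", "block", "period", "stimulus",
                 "responded", "rt")]
    class(ev) <- c("gsat_events", "data.frame")
    ev
  })
}

# Randomly assign trial types within one block such that every repeat No-Go
# is immediately preceded by a Go (congruent) trial.
place_nogo_trials <- function(n, n_nogo, n_repeat) {
  n_incong <- n_nogo - n_repeat
  if (n_nogo > n) stop("more No-Go trials than trials in the block")
  # feasibility: each repeat needs a distinct Go predecessor
  if (n_repeat > (n - n_nogo))
    stop("more repeat No-Go trials than available congruent predecessors")
  for (attempt in 1:200) {
    type <- rep("go", n)
    nogo_pos <- sample.int(n, n_nogo)
    type[nogo_pos] <- "nogo_incongruent"
    # choose which No-Go positions become repeats: need pos > 1 and a Go
    # predecessor (i.e. predecessor not itself a No-Go)
    ok <- nogo_pos[nogo_pos > 1L & !(nogo_pos - 1L) %in% nogo_pos]
    if (length(ok) < n_repeat) next
    rep_pos <- if (n_repeat > 0) ok[sample.int(length(ok), n_repeat)] else integer(0)
    type[rep_pos] <- "nogo_repeat"
    return(type)
  }
  stop("could not place repeat No-Go trials after 200 attempts; ",
       "constraint set may be infeasible")
}
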