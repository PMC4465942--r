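# Builders for small, fully controlled trial tables.

# One forced-trial row in the canonical schema.
trial_row <- function(subject = "A", session = "A_001", ord = 1L,
                      phase = "TEST", idx = 1L, valence = "POS",
                      side = "right", latency = 2, responded = TRUE) {
  data.frame(
    subject_id = subject, session_id = session, session_ordinal = ord,
    phase = phase, trial_index = idx, trial_kind = "forced",
    valence = valence, pos_side = NA_character_, side = side,
    responded = responded,
    latency_s = if (responded) latency else NA_real_,
    coded_latency_s = if (responded) latency else 61,
    first_touch = NA_character_, stringsAsFactors = FALSE
  )
}

# A block-training session with explicit POS/NEG latencies (vectors of 12).
block_session <- function(pos_lat, neg_lat, subject = "A", ord = 1L,
                          phase = "BLOCK6") {
  sched <- make_block_schedule(if (phase == "BLOCK6") 6 else 3,
                               session_ordinal = ord, seed = ord)
  lat <- numeric(nrow(sched))
  lat[sched$valence == "POS"] <- pos_lat
  lat[sched$valence == "NEG"] <- neg_lat
  do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    trial_row(subject, sprintf("%s_%03d", subject, ord), ord, phase, i,
              sched$valence[i], sched$side[i], latency = lat[i],
              responded = lat[i] <= 60)
  }))
}

# A choice session with k POS-first touches out of 24.
choice_session <- function(k, subject = "A", ord = 1L) {
  sched <- make_choice_schedule(seed = ord)
  rows <- schedule_to_trials(sched, subject, sprintf("%s_%03d", subject, ord),
                             ord)
  rows$planned <- NULL
  rows$responded <- TRUE
  rows$latency_s <- 2
  rows$coded_latency_s <- 2
  rows$first_touch <- c(rep("POS", k), rep("NEG", 24 - k))
  rows
}

# A test session whose responded latencies are fixed per valence.
test_session <- function(lat_by_valence, subject = "A", ord = 1L,
                         seed = NULL, nonrespond_idx = integer(0)) {
  sched <- make_test_schedule(seed = seed %||% ord)
  rows <- schedule_to_trials(sched, subject, sprintf("%s_%03d", subject, ord),
                             ord)
  rows$planned <- NULL
  lat <- unname(lat_by_valence[rows$valence])
  rows$responded <- TRUE
  rows$latency_s <- lat
  rows$coded_latency_s <- lat
  if (length(nonrespond_idx)) {
    rows$responded[nonrespond_idx] <- FALSE
    rows$latency_s[nonrespond_idx] <- NA_real_
    rows$coded_latency_s[nonrespond_idx] <- 61
  }
  rows
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Force a protocol state into a given machine phase with clean accumulators.
reset_phase_for_test <- function(state, phase) {
  state$phase <- phase
  state$sessions_in_phase <- 0L
  state$successive_significant <- 0L
  state$pool <- state$pool[0, , drop = FALSE]
  state
}

# Low-noise behaviour parameters used by recovery-style tests.
quiet_params <- function(p_true = 0.5, ...) {
  behavior_params(p_true = p_true, sigma_trial = 0.05, sigma_sess = 0.05,
                  p_nonresponse = 0, ...)
}
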