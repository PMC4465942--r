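#' Training-progression state
#'
#' Tracks where a subject is in the training -> choice -> test progression:
#' the current phase (`BLOCK6`, `BLOCK3`, `CHOICE0`, `CHOICE`/`TEST` within
#' test cycle `k`, or `DONE`), the cumulative pool of training latencies
#' for the current block phase, the count of successive sessions meeting
#' the cumulative criterion, a per-session history and a decisions log.
#'
#' @param subject_id Subject identifier.
#' @param config A [protocol_config()].
#' @return A list of class `jb_protocol_state`.
#' @export
new_protocol_state <- function(subject_id, config = protocol_config()) {
  state <- list(
    subject_id = subject_id,
    config = config,
    phase = "BLOCK6",
    test_cycle = 0L,
    session_count = 0L,
    sessions_in_phase = 0L,
    successive_significant = 0L,
    pool = data.frame(valence = character(0), coded_latency_s = numeric(0),
                      stringsAsFactors = FALSE),
    history = data.frame(session = integer(0), phase = character(0),
                         statistic = numeric(0), p_value = numeric(0),
                         direction_predicted = logical(0),
                         pos_choices = integer(0), decision = character(0),
                         stringsAsFactors = FALSE),
    log = data.frame(session = integer(0), phase = character(0),
                     decision = character(0), reason = character(0),
                     stringsAsFactors = FALSE),
    complete = FALSE
  )
  class(state) <- "jb_protocol_state"
  state
}

# The phase label a session must carry to be fed to the state machine in a
# given machine phase.
session_phase_for <- function(state_phase) {
  switch(state_phase,
         BLOCK6 = "BLOCK6", BLOCK3 = "BLOCK3",
         CHOICE0 = "CHOICE", CHOICE = "CHOICE", TEST = "TEST",
         DONE = NA_character_)
}

#' Evaluate the cumulative block-training criterion
#'
#' Adds a session's trials to the cumulative pool of the current block
#' phase and runs the two-tailed two-sample t-test of POS versus NEG coded
#' latencies on all data collected so far in the phase.  A session counts
#' toward progression iff the cumulative test has `p < alpha` *and* the
#' difference is in the predicted direction (mean POS latency shorter than
#' mean NEG).  The six-trial-block phase advances after three successive
#' counting sessions (a non-counting session resets the run) and no fewer
#' than its minimum number of sessions; the three-trial-block phase
#' advances after one counting session.
#'
#' Non-responses enter the pool at the 61-s code.  The test runs on raw
#' seconds by default (`config$training_scale = "reciprocal"` transforms
#' the pool first); the direction check is always on raw-second means.
#'
#' @param state A `jb_protocol_state` currently in `BLOCK6` or `BLOCK3`.
#' @param session_trials Trial data frame for the new session (canonical
#'   schema), all in the state's current phase.
#' @return A list with elements `state` (updated), `decision`
#'   (`"continue"` or `"advance"`) and `test` (the `jb_t_test`).
#' @export
evaluate_block_criterion <- function(state, session_trials) {
  phase <- state$phase
  if (!phase %in% c("BLOCK6", "BLOCK3")) {
    stop("state error: not in a block-training phase (", phase, ")")
  }
  if (any(session_trials$phase != phase)) {
    stop("state error: session trials are not ", phase, " trials")
  }
  cfg <- state$config
  state$pool <- rbind(state$pool,
                      session_trials[c("valence", "coded_latency_s")])
  state$sessions_in_phase <- state$sessions_in_phase + 1L

  pos <- state$pool$coded_latency_s[state$pool$valence == "POS"]
  neg <- state$pool$coded_latency_s[state$pool$valence == "NEG"]
  if (length(pos) < 2 || length(neg) < 2) {
    stop("insufficient data: need >= 2 trials per valence in the cumulative pool")
  }
  tp <- if (cfg$training_scale == "reciprocal") reciprocal_transform(pos) else pos
  tn <- if (cfg$training_scale == "reciprocal") reciprocal_transform(neg) else neg
  tt <- two_sample_t(tp, tn, variant = cfg$t_variant)
  counts <- tt$p_two_tailed < cfg$alpha && mean(pos) < mean(neg)

  state$successive_significant <-
    if (counts) state$successive_significant + 1L else 0L

  advance <- if (phase == "BLOCK6") {
    state$successive_significant >= cfg$block6_required_successive &&
      state$sessions_in_phase >= cfg$block6_min_sessions
  } else {
    state$successive_significant >= 1L &&
      state$sessions_in_phase >= cfg$block3_min_sessions
  }
  list(state = state,
       decision = if (advance) "advance" else "continue",
       test = tt,
       counts = counts)
}

#' Evaluate the choice-session criterion
#'
#' Exact two-tailed binomial test of the number of trials on which the POS
#' cone was touched first, against chance (1/2).  The session passes iff
#' the count reaches [min_significant_choices()] for the session length --
#' 18 of 24 at `alpha = 0.05`.  Non-responses count as non-POS choices.
#'
#' @param session_trials Trial data frame of one choice session.
#' @param config A [protocol_config()].
#' @return A list with `decision` (`"pass"`/`"fail"`), `pos_choices`,
#'   `threshold` and `test` (a `jb_binomial`).
#' @export
evaluate_choice_criterion <- function(session_trials,
                                      config = protocol_config()) {
  if (nrow(session_trials) != config$choice_session_trials) {
    stop("choice session must have ", config$choice_session_trials,
         " trials (got ", nrow(session_trials), ")")
  }
  k <- sum(session_trials$first_touch == "POS", na.rm = TRUE)
  n <- nrow(session_trials)
  thr <- min_significant_choices(n, config$alpha)
  test <- binomial_two_tailed(k, n)
  list(decision = if (!is.na(thr) && k >= thr) "pass" else "fail",
       pos_choices = k, threshold = thr, test = test)
}

#' Advance the progression state machine by one session
#'
#' Feeds one observed session to the state machine and applies the
#' progression rules: `BLOCK6` advances to `BLOCK3` on its cumulative
#' criterion, `BLOCK3` to the first choice session (`CHOICE0`), a passed
#' `CHOICE0` enters the test phase (whose first session is another choice
#' session), a failed `CHOICE0` returns to `BLOCK3`, each test session
#' must be preceded by a passed choice session (a failed in-cycle choice
#' session is repeated), and the machine reaches `DONE` after the final
#' test session.  Every decision is appended to the state's log with its
#' reason.
#'
#' @param state A `jb_protocol_state`.
#' @param session_trials Trial data frame for the session just run; its
#'   `phase` column must match the session type the machine expects.
#' @return The updated `jb_protocol_state`.
#' @export
advance_state <- function(state, session_trials) {
  if (state$phase == "DONE") stop("state error: protocol already complete")
  expected <- session_phase_for(state$phase)
  got <- unique(session_trials$phase)
  if (length(got) != 1 || got != expected) {
    stop("state error: expected a ", expected, " session in machine phase ",
         state$phase, ", got ", paste(got, collapse = "/"))
  }
  cfg <- state$config
  state$session_count <- state$session_count + 1L
  sess <- state$session_count
  hist <- function(statistic = NA_real_, p = NA_real_, dir = NA,
                   pos_choices = NA_integer_, decision) {
    data.frame(session = sess, phase = state$phase, statistic = statistic,
               p_value = p, direction_predicted = dir,
               pos_choices = pos_choices, decision = decision,
               stringsAsFactors = FALSE)
  }
  log_entry <- function(decision, reason) {
    data.frame(session = sess, phase = state$phase, decision = decision,
               reason = reason, stringsAsFactors = FALSE)
  }

  if (state$phase %in% c("BLOCK6", "BLOCK3")) {
    ev <- evaluate_block_criterion(state, session_trials)
    tt <- ev$test
    old_phase <- state$phase
    state <- ev$state
    reason <- sprintf(
      "cumulative t(%0.1f) = %0.3f, p = %0.4f, %s direction; %d successive of %d required",
      tt$df, tt$t, tt$p_two_tailed,
      if (tt$direction_predicted) "predicted" else "wrong",
      state$successive_significant,
      if (old_phase == "BLOCK6") cfg$block6_required_successive else 1L)
    state$history <- rbind(state$history,
                           hist(tt$t, tt$p_two_tailed,
                                tt$direction_predicted, decision = ev$decision))
    state$log <- rbind(state$log, log_entry(ev$decision, reason))
    if (ev$decision == "advance") {
      state <- reset_phase(state,
                           if (old_phase == "BLOCK6") "BLOCK3" else "CHOICE0")
    }
  } else if (state$phase %in% c("CHOICE0", "CHOICE")) {
    ev <- evaluate_choice_criterion(session_trials, cfg)
    reason <- sprintf("%d of %d POS-first choices, threshold %d (p = %0.4f)",
                      ev$pos_choices, ev$test$n, ev$threshold,
                      ev$test$p_two_tailed)
    state$history <- rbind(state$history,
                           hist(ev$pos_choices, ev$test$p_two_tailed,
                                pos_choices = ev$pos_choices,
                                decision = ev$decision))
    state$log <- rbind(state$log, log_entry(ev$decision, reason))
    if (state$phase == "CHOICE0") {
      if (ev$decision == "pass") {
        state$test_cycle <- 1L
        state <- reset_phase(state, "CHOICE")
      } else {
        state <- reset_phase(state, "BLOCK3")
      }
    } else {
      if (ev$decision == "pass") {
        state <- reset_phase(state, "TEST")
      }
      # a failed in-cycle choice session is repeated: phase unchanged
    }
  } else if (state$phase == "TEST") {
    k <- state$test_cycle
    decision <- if (k >= cfg$n_test_sessions) "done" else "next_cycle"
    reason <- sprintf("test session %d of %d complete", k, cfg$n_test_sessions)
    state$history <- rbind(state$history, hist(decision = decision))
    state$log <- rbind(state$log, log_entry(decision, reason))
    if (k >= cfg$n_test_sessions) {
      state <- reset_phase(state, "DONE")
      state$complete <- TRUE
    } else {
      state$test_cycle <- k + 1L
      state <- reset_phase(state, "CHOICE")
    }
  }
  state
}

# Move to a new machine phase, clearing phase-local accumulators.
reset_phase <- function(state, new_phase) {
  state$phase <- new_phase
  state$sessions_in_phase <- 0L
  state$successive_significant <- 0L
  state$pool <- state$pool[0, , drop = FALSE]
  state
}

#' @export
print.jb_protocol_state <- function(x, ...) {
  cat("<jb_protocol_state> subject", x$subject_id,
      "| phase", x$phase,
      if (x$phase %in% c("CHOICE", "TEST")) paste0("(cycle ", x$test_cycle, ")")
      else "",
      "| sessions run:", x$session_count, "\n")
  invisible(x)
}
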