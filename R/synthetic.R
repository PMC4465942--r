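#' Generative parameters of a simulated subject
#'
#' @description
#' The simulator models a subject whose latency to touch a cone is
#' lognormal around a valence-dependent expectation:
#'
#' * POS expectation `exp(mu_log_lat)` seconds;
#' * NEG expectation POS + `discrimination_frac * delta`, where the
#'   discrimination fraction `1 - exp(-trials_seen / tau)` grows with
#'   training experience;
#' * intermediate cones sit at standardized levels
#'   `p_true - gradient` (NP), `p_true` (M), `p_true + gradient` (NN)
#'   between the POS and NEG expectations, so the trial-weighted mean of
#'   the three recovers `p_true` exactly in expectation.
#'
#' Day-to-day motivation is a multiplicative session effect
#' (`exp(N(0, sigma_sess))`), trial noise is `exp(N(0, sigma_trial))`,
#' and a trial is a non-response (coded 61 s in training, excluded in
#' test analyses) if an attention lapse occurs (probability
#' `p_nonresponse`) or the drawn latency exceeds the 60-s cutoff.  On
#' choice trials the probability of touching the POS cone first is
#' `plogis(beta_choice * discrimination_frac)`, so the preference
#' strengthens as the discrimination is learned.
#'
#' @param mu_log_lat Baseline log-latency of a fully learned POS response
#'   (log-seconds).
#' @param delta Asymptotic NEG-POS difference in expected latency
#'   (seconds, >= 0).
#' @param p_true True pessimism: the standardized level of the mid
#'   intermediate cone, typically in \[-0.2, 1.2\].
#' @param gradient Half-spread of NP/NN around `p_true` (standardized
#'   units, >= 0).
#' @param tau Learning time constant (trials).
#' @param sigma_sess SD of the session-level motivation effect
#'   (log scale).
#' @param sigma_trial SD of trial-level noise (log scale).
#' @param p_nonresponse Probability of an attention lapse per trial.
#' @param beta_choice Choice sensitivity (dimensionless).
#' @param n_pilot_trials Pre-training (pilot) trials credited to the
#'   learning state before block training starts; counted in total
#'   training trials.
#' @return A list of class `jb_behavior_params`.
#' @export
behavior_params <- function(mu_log_lat = log(3.5),
                            delta = 4,
                            p_true = 0.5,
                            gradient = 0.15,
                            tau = 80,
                            sigma_sess = 0.15,
                            sigma_trial = 0.3,
                            p_nonresponse = 0.02,
                            beta_choice = 5,
                            n_pilot_trials = 20L) {
  p <- list(mu_log_lat = mu_log_lat, delta = delta, p_true = p_true,
            gradient = gradient, tau = tau, sigma_sess = sigma_sess,
            sigma_trial = sigma_trial, p_nonresponse = p_nonresponse,
            beta_choice = beta_choice,
            n_pilot_trials = as.integer(n_pilot_trials))
  if (p$delta < 0 || p$gradient < 0 || p$tau <= 0 || p$sigma_sess < 0 ||
      p$sigma_trial < 0 || p$p_nonresponse < 0 || p$p_nonresponse >= 1 ||
      p$n_pilot_trials < 0) {
    stop("invalid behaviour parameters: sds/rates must be >= 0, ",
         "p_nonresponse in [0, 1), tau > 0")
  }
  class(p) <- "jb_behavior_params"
  p
}

#' Learning state of a simulated subject
#'
#' @param trials_seen Number of discrimination-relevant trials experienced
#'   so far.
#' @param params A [behavior_params()].
#' @return A list with `trials_seen` and `discrimination_frac`
#'   (`1 - exp(-trials_seen / tau)`, non-decreasing in `trials_seen`).
#' @export
learning_state <- function(trials_seen, params) {
  list(trials_seen = trials_seen,
       discrimination_frac = 1 - exp(-trials_seen / params$tau))
}

#' Expected latency to a cone
#'
#' @param valence Stimulus label (POS/NP/M/NN/NEG).
#' @param params A [behavior_params()].
#' @param state A [learning_state()].
#' @return Expected latency in seconds (before session/trial noise).
#' @export
expected_latency <- function(valence, params, state) {
  l_pos <- exp(params$mu_log_lat)
  l_neg <- l_pos + state$discrimination_frac * params$delta
  s <- c(POS = 0,
         NP = params$p_true - params$gradient,
         M = params$p_true,
         NN = params$p_true + params$gradient,
         NEG = 1)
  if (any(!valence %in% names(s))) stop("unknown valence: ", valence)
  unname(l_pos + s[valence] * (l_neg - l_pos))
}

#' Draw one forced trial
#'
#' @inheritParams expected_latency
#' @param session_effect Session-level motivation effect (log scale).
#' @param config A [protocol_config()].
#' @return A list with `responded`, `latency_s` (`NA` on non-response)
#'   and `coded_latency_s`.  Draws consume the current RNG stream.
#' @export
draw_trial <- function(valence, params, state, session_effect = 0,
                       config = protocol_config()) {
  lat <- expected_latency(valence, params, state) *
    exp(session_effect + stats::rnorm(1, 0, params$sigma_trial))
  lapse <- stats::runif(1) < params$p_nonresponse
  if (lapse || lat > config$response_cutoff_s) {
    list(responded = FALSE, latency_s = NA_real_,
         coded_latency_s = config$nonresponse_code_s)
  } else {
    list(responded = TRUE, latency_s = lat, coded_latency_s = lat)
  }
}

#' Draw the first touch of a choice trial
#'
#' @inheritParams draw_trial
#' @return `"POS"` or `"NEG"`.
#' @export
draw_choice <- function(params, state) {
  p_pos <- stats::plogis(params$beta_choice * state$discrimination_frac)
  if (stats::runif(1) < p_pos) "POS" else "NEG"
}

# Internal: simulate one session from a schedule; returns trial rows and the
# updated trials_seen.  Learning accrues on every reinforced-contingency
# trial (block training, choice, and POS/NEG test trials) but not on the
# never-reinforced intermediate probes.
simulate_session <- function(schedule, params, trials_seen, subject_id,
                             session_id, session_ordinal, config) {
  phase <- attr(schedule, "phase")
  sess_eff <- stats::rnorm(1, 0, params$sigma_sess)
  n <- nrow(schedule)
  rows <- schedule_to_trials(schedule, subject_id, session_id,
                             session_ordinal)
  rows$planned <- NULL
  for (i in seq_len(n)) {
    st <- learning_state(trials_seen, params)
    if (phase == "CHOICE") {
      # latency is to the first cone touched
      lapse <- stats::runif(1) < params$p_nonresponse
      touched <- draw_choice(params, st)
      lat <- expected_latency(touched, params, st) *
        exp(sess_eff + stats::rnorm(1, 0, params$sigma_trial))
      if (lapse || lat > config$response_cutoff_s) {
        rows$responded[i] <- FALSE
        rows$coded_latency_s[i] <- config$nonresponse_code_s
      } else {
        rows$responded[i] <- TRUE
        rows$latency_s[i] <- lat
        rows$coded_latency_s[i] <- lat
        rows$first_touch[i] <- touched
      }
      trials_seen <- trials_seen + 1L
    } else {
      tr <- draw_trial(rows$valence[i], params, st, sess_eff, config)
      rows$responded[i] <- tr$responded
      rows$latency_s[i] <- tr$latency_s
      rows$coded_latency_s[i] <- tr$coded_latency_s
      if (!(phase == "TEST" && rows$valence[i] %in% .intermediate_labels)) {
        trials_seen <- trials_seen + 1L
      }
    }
  }
  list(rows = rows, trials_seen = trials_seen)
}

#' Simulate one subject through the full protocol
#'
#' Runs the complete progression: six-trial-block sessions until the
#' cumulative criterion is met, three-trial blocks, the first choice
#' session, then five choice-test cycles, generating every schedule,
#' drawing every trial from the behavioural model and evaluating every
#' progression criterion exactly as for real data.  Learning accrues
#' per trial; pilot experience is credited up front via
#' `params$n_pilot_trials`.
#'
#' @param params A [behavior_params()].
#' @param config A [protocol_config()].
#' @param seed Integer seed (`NULL` to consume the current RNG stream).
#' @param session_cap Maximum number of sessions before giving up; a
#'   capped run is flagged, not an error.
#' @param stop_after Optionally stop early once a machine phase has been
#'   left, e.g. `"BLOCK6"`; useful for studying the training criterion in
#'   isolation.
#' @return A list of class `jb_simulation`: `trials` (canonical schema),
#'   `state` (final `jb_protocol_state`), `completed`, `capped`,
#'   `n_sessions`, `total_training_trials` (pilot + block-training
#'   trials) and `params`.
#' @export
simulate_subject <- function(params, config = protocol_config(),
                             seed = NULL, session_cap = 60L,
                             stop_after = NULL) {
  with_seed(seed, {
    subject_id <- "sim"
    state <- new_protocol_state(subject_id, config)
    trials_seen <- params$n_pilot_trials
    training_trials <- params$n_pilot_trials
    block_ordinal <- 0L
    all_rows <- list()

    while (state$phase != "DONE" && state$session_count < session_cap) {
      phase <- state$phase
      if (!is.null(stop_after) && !phase %in% stop_after) break
      sched <- switch(session_phase_for(phase),
        BLOCK6 = {
          block_ordinal <- block_ordinal + 1L
          make_block_schedule(config$block6_size, block_ordinal,
                              config = config)
        },
        BLOCK3 = {
          block_ordinal <- block_ordinal + 1L
          make_block_schedule(config$block3_size, block_ordinal,
                              config = config)
        },
        CHOICE = make_choice_schedule(config = config),
        TEST = make_test_schedule(config = config)
      )
      ord <- state$session_count + 1L
      session_id <- sprintf("%s_%03d_%s", subject_id, ord,
                            tolower(session_phase_for(phase)))
      sim <- simulate_session(sched, params, trials_seen, subject_id,
                              session_id, ord, config)
      trials_seen <- sim$trials_seen
      if (phase %in% c("BLOCK6", "BLOCK3")) {
        training_trials <- training_trials + nrow(sim$rows)
      }
      all_rows[[length(all_rows) + 1L]] <- sim$rows
      state <- advance_state(state, sim$rows)
    }

    trials <- do.call(rbind, all_rows)
    class(trials) <- c("jb_trials", "data.frame")
    structure(list(trials = trials, state = state,
                   completed = state$complete,
                   capped = !state$complete && is.null(stop_after) &&
                     state$session_count >= session_cap,
                   n_sessions = state$session_count,
                   total_training_trials = training_trials,
                   params = params),
              class = "jb_simulation")
  })
}

#' Simulate a multi-subject study
#'
#' Generates a full dataset shaped like the deposited study: by default 3
#' subjects, each trained to criterion and run through five test sessions
#' of 25 trials (8 POS, 8 NEG, 3 each NP/M/NN), together with a
#' ground-truth sidecar of the generating parameters for recovery tests.
#'
#' @param n_subjects Number of subjects.
#' @param params A single [behavior_params()] applied to all subjects, or
#'   a list of one per subject.  The default varies `p_true` over
#'   `c(0.2, 0.5, 0.8)` (recycled) so subjects span the
#'   optimistic-pessimistic range.
#' @param seed Integer seed; per-subject streams are derived from it.
#' @param config A [protocol_config()].
#' @param session_cap Per-subject session cap.
#' @return A list of class `jb_study`: `trials` (all subjects, canonical
#'   schema), `truth` (data frame of generating parameters plus
#'   completion flags), and `subjects` (the per-subject
#'   `jb_simulation`s).
#' @export
generate_study <- function(n_subjects = 3L, params = NULL, seed = 1L,
                           config = protocol_config(), session_cap = 60L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (is.null(params)) {
    p_grid <- rep(c(0.2, 0.5, 0.8), length.out = n_subjects)
    params <- lapply(p_grid, function(p) behavior_params(p_true = p))
  } else if (inherits(params, "jb_behavior_params")) {
    params <- rep(list(params), n_subjects)
  }
  if (length(params) != n_subjects) {
    stop("params must be one behavior_params or a list of n_subjects")
  }
  with_seed(seed, {
    seeds <- spawn_seeds(n_subjects)
    subjects <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      sim <- simulate_subject(params[[i]], config, seed = seeds[i],
                              session_cap = session_cap)
      sid <- sprintf("S%d", i)
      sim$trials$subject_id <- sid
      sim$trials$session_id <- sub("^sim", sid, sim$trials$session_id)
      sim$state$subject_id <- sid
      subjects[[i]] <- sim
    }
    trials <- do.call(rbind, lapply(subjects, `[[`, "trials"))
    rownames(trials) <- NULL
    class(trials) <- c("jb_trials", "data.frame")
    truth <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      p <- params[[i]]
      data.frame(subject_id = sprintf("S%d", i),
                 p_true = p$p_true, delta = p$delta,
                 mu_log_lat = p$mu_log_lat, gradient = p$gradient,
                 tau = p$tau, sigma_sess = p$sigma_sess,
                 sigma_trial = p$sigma_trial,
                 p_nonresponse = p$p_nonresponse,
                 beta_choice = p$beta_choice,
                 n_pilot_trials = p$n_pilot_trials,
                 completed = subjects[[i]]$completed,
                 total_training_trials = subjects[[i]]$total_training_trials,
                 stringsAsFactors = FALSE)
    }))
    structure(list(trials = trials, truth = truth, subjects = subjects,
                   seed = seed),
              class = "jb_study")
  })
}

#' @export
print.jb_simulation <- function(x, ...) {
  cat("<jb_simulation>", x$n_sessions, "sessions;",
      if (x$completed) "completed" else if (x$capped) "capped (incomplete)"
      else "stopped early",
      "| training trials:", x$total_training_trials, "\n")
  invisible(x)
}

#' @export
print.jb_study <- function(x, ...) {
  cat("<jb_study>", nrow(x$truth), "subjects,", nrow(x$trials), "trials\n")
  print(x$truth[c("subject_id", "p_true", "completed",
                  "total_training_trials")])
  invisible(x)
}
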