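#' Run configuration
#'
#' Builds (or reads from YAML) the configuration driving the pipeline
#' commands.  Exactly one of `input` (path to a trial CSV) or `simulation`
#' (a list with at least `n_subjects` and `seed`) must be present.
#'
#' @param input Optional path to an existing trial CSV.
#' @param simulation Optional list: `n_subjects`, `seed`, and optionally
#'   any [behavior_params()] arguments (applied to all subjects) or
#'   `p_true` as a vector (one per subject).
#' @param analysis List of analysis options: `alpha`, `t_variant`
#'   (`"welch"`/`"pooled"`), `index_scale` (`"raw"`), `model_scale`
#'   (`"reciprocal"`), `speed_scale` (`"reciprocal"`).
#' @param out_dir Output directory for written reports.
#' @return A list of class `jb_run_config`.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       analysis = list(), out_dir = NULL) {
  if (is.null(input) == is.null(simulation)) {
    stop("usage error: exactly one of 'input' or 'simulation' must be given")
  }
  if (!is.null(simulation) && is.null(simulation$seed)) {
    stop("usage error: field 'seed' is required in the simulation block")
  }
  defaults <- list(alpha = 0.05, t_variant = "welch", index_scale = "raw",
                   model_scale = "reciprocal", speed_scale = "reciprocal")
  analysis <- utils::modifyList(defaults, analysis)
  structure(list(input = input, simulation = simulation,
                 analysis = analysis, out_dir = out_dir),
            class = "jb_run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file with top-level keys `input` or
#'   `simulation`, plus optional `analysis` and `out_dir`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(input = y$input, simulation = y$simulation,
             analysis = y$analysis %||% list(), out_dir = y$out_dir)
}

#' Simulate a study and write its files
#'
#' Generates a study from the configuration's simulation block and writes
#' `trials.csv` (canonical schema), `truth.csv` (generating parameters)
#' and `provenance.json` (seed, settings, file checksums) into the output
#' directory.  Identical configurations yield identical files.
#'
#' @param config A [run_config()] with a simulation block.
#' @param out_dir Output directory (falls back to `config$out_dir`).
#' @return Invisibly, the [generate_study()] result with `$files` added.
#' @export
cmd_simulate <- function(config, out_dir = config$out_dir) {
  if (is.null(config$simulation)) {
    stop("usage error: config has no simulation block")
  }
  if (is.null(out_dir)) stop("usage error: no output directory")
  sim <- config$simulation
  n <- sim$n_subjects %||% 3L
  params <- if (!is.null(sim$p_true)) {
    extra <- sim[setdiff(names(sim), c("n_subjects", "seed", "p_true"))]
    lapply(rep(sim$p_true, length.out = n), function(p) {
      do.call(behavior_params, c(list(p_true = p), extra))
    })
  } else {
    extra <- sim[setdiff(names(sim), c("n_subjects", "seed"))]
    if (length(extra)) rep(list(do.call(behavior_params, extra)), n) else NULL
  }
  study <- generate_study(n_subjects = n, params = params, seed = sim$seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials_path <- file.path(out_dir, "trials.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_trials(study$trials, trials_path)
  utils::write.csv(study$truth, truth_path, row.names = FALSE)
  prov <- list(seed = sim$seed, n_subjects = n,
               analysis = config$analysis,
               md5 = as.list(tools::md5sum(c(trials_path, truth_path))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  study$files <- c(trials = trials_path, truth = truth_path)
  invisible(study)
}

#' Training summary statistics
#'
#' Summarises per-subject training effort the way a study report would:
#' mean sessions to criterion in each block-training sub-phase, mean and
#' range of total training trials (pilot plus block training).
#'
#' @param per_subject Data frame with one row per subject and columns
#'   `block6_sessions`, `block3_sessions`, `total_training_trials`.
#' @return A list with `mean_block6_sessions`, `mean_block3_sessions`,
#'   `mean_total_training_trials`, `min_total_training_trials`,
#'   `max_total_training_trials`.
#' @export
#' @examples
#' training_summary(data.frame(block6_sessions = c(6, 3, 7),
#'                             block3_sessions = c(3, 1, 1),
#'                             total_training_trials = c(237, 107, 240)))
training_summary <- function(per_subject) {
  need <- c("block6_sessions", "block3_sessions", "total_training_trials")
  if (!all(need %in% names(per_subject))) {
    stop("per_subject needs columns ", paste(need, collapse = ", "))
  }
  list(
    mean_block6_sessions = mean(per_subject$block6_sessions),
    mean_block3_sessions = mean(per_subject$block3_sessions),
    mean_total_training_trials = mean(per_subject$total_training_trials),
    min_total_training_trials = min(per_subject$total_training_trials),
    max_total_training_trials = max(per_subject$total_training_trials)
  )
}

# Internal: per-subject training/choice summary table from trial data.
training_table_from_trials <- function(trials, config,
                                       pilot_trials = NULL) {
  subjects <- unique(trials$subject_id)
  rows <- lapply(subjects, function(s) {
    d <- trials[trials$subject_id == s, , drop = FALSE]
    sess_phase <- tapply(d$phase, d$session_id, function(p) p[1])
    n6 <- sum(sess_phase == "BLOCK6")
    n3 <- sum(sess_phase == "BLOCK3")
    pil <- if (is.null(pilot_trials)) 0L else pilot_trials[[s]] %||% 0L
    total <- pil + sum(d$phase %in% c("BLOCK6", "BLOCK3"))
    # first choice session after training
    ch <- d[d$phase == "CHOICE", , drop = FALSE]
    choice0 <- NA_real_; choice0_p <- NA_real_
    if (nrow(ch)) {
      first_id <- ch$session_id[which.min(ch$session_ordinal)]
      c0 <- ch[ch$session_id == first_id, , drop = FALSE]
      k <- sum(c0$first_touch == "POS", na.rm = TRUE)
      choice0 <- k / nrow(c0)
      choice0_p <- binomial_two_tailed(k, nrow(c0))$p_two_tailed
    }
    data.frame(subject_id = s, pilot_trials = pil, block6_sessions = n6,
               block3_sessions = n3, total_training_trials = total,
               choice0_prop_pos = choice0, choice0_p = choice0_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analyze a study dataset
#'
#' Runs the full analysis pipeline on a trial table: protocol conformance,
#' a per-subject training summary, per-session choice-criterion outcomes
#' and the choice-trend mixed model, per-subject POS-NEG t-tests on the
#' test data, pessimism summaries and standardized latencies, per-session
#' and cumulative statistic trajectories, and the two fixed-effect latency
#' models with Tukey HSD contrasts between subjects.  Every statistic in
#' the report is annotated with the scale it was computed on.
#'
#' @param trials A trial table (canonical schema) or a path to one.
#' @param config A [run_config()] (analysis options) -- optional.
#' @param protocol A [protocol_config()].
#' @param pilot_trials Optional named list/vector of pilot-trial counts
#'   per subject, added to total training trials.
#' @param override_conformance If `FALSE` (default) a non-conformant
#'   dataset is an error; set `TRUE` to analyse anyway (the report keeps
#'   the violation list).
#' @param out_dir Optional directory: writes `report.json` and tidy CSVs.
#' @return A list of class `jb_report`.
#' @export
cmd_analyze <- function(trials, config = run_config(input = "unused"),
                        protocol = protocol_config(), pilot_trials = NULL,
                        override_conformance = FALSE, out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials(trials, config = protocol)
  opts <- config$analysis
  conf <- validate_protocol_conformance(trials, protocol)
  if (nrow(conf) > 0 && !override_conformance) {
    stop("dataset is not protocol-conformant (", nrow(conf),
         " violation(s)); pass override_conformance = TRUE to analyse anyway.",
         " First: ", conf$rule[1], " - ", conf$detail[1])
  }

  subjects <- sort(unique(trials$subject_id))
  train_tab <- training_table_from_trials(trials, protocol, pilot_trials)
  train_sum <- training_summary(train_tab)

  # choice sessions: per-session criterion outcomes + trend model
  choice <- trials[trials$phase == "CHOICE", , drop = FALSE]
  choice_rows <- list()
  for (s in subjects) {
    cd <- choice[choice$subject_id == s, , drop = FALSE]
    ords <- sort(unique(cd$session_ordinal))
    for (j in seq_along(ords)) {
      cs <- cd[cd$session_ordinal == ords[j], , drop = FALSE]
      ev <- tryCatch(evaluate_choice_criterion(cs, protocol),
                     error = function(e) NULL)
      if (is.null(ev)) next
      choice_rows[[length(choice_rows) + 1L]] <- data.frame(
        subject_id = s, session_number = j - 1L,  # first is "choice 0"
        prop_pos = ev$pos_choices / ev$test$n,
        pos_choices = ev$pos_choices, p_value = ev$test$p_two_tailed,
        pass = ev$decision == "pass", stringsAsFactors = FALSE)
    }
  }
  choice_tab <- if (length(choice_rows)) do.call(rbind, choice_rows) else NULL
  choice_trend <- tryCatch(fit_choice_trend(choice_tab),
                           error = function(e) paste("not fitted:",
                                                     conditionMessage(e)))

  # test data
  kept <- filter_test_trials(trials)
  posneg_tests <- lapply(subjects, function(s) {
    d <- kept[kept$subject_id == s, , drop = FALSE]
    tryCatch({
      tt <- two_sample_t(d$latency_s[d$valence == "POS"],
                         d$latency_s[d$valence == "NEG"],
                         variant = opts$t_variant)
      list(subject_id = s, t = tt$t, df = tt$df, p = tt$p_two_tailed,
           mean_pos = tt$mean_a, mean_neg = tt$mean_b, scale = "raw_seconds")
    }, error = function(e) list(subject_id = s,
                                error = conditionMessage(e)))
  })

  pessimism <- lapply(subjects, function(s) {
    tryCatch(subject_pessimism(trials, s),
             error = function(e) structure(
               list(subject_id = s, error = conditionMessage(e)),
               class = "jb_insufficient"))
  })
  names(pessimism) <- subjects

  trajectories <- lapply(subjects, function(s) {
    tryCatch(trajectory(trials, s, scale = opts$speed_scale),
             error = function(e) NULL)
  })
  trajectories <- do.call(rbind, trajectories)

  # per-session speed covariate table
  speed_rows <- list()
  test <- trials[trials$phase == "TEST", , drop = FALSE]
  for (key in unique(paste(test$subject_id, test$session_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sd_ <- test[test$subject_id == parts[1] & test$session_id == parts[2], ,
                drop = FALSE]
    sp <- tryCatch(session_speed(sd_, scale = opts$speed_scale),
                   error = function(e) NULL)
    if (!is.null(sp)) {
      speed_rows[[length(speed_rows) + 1L]] <- data.frame(
        subject_id = parts[1], session_id = parts[2], speed = sp$speed,
        n_used = sp$n_used, stringsAsFactors = FALSE)
    }
  }
  speeds <- if (length(speed_rows)) do.call(rbind, speed_rows) else NULL

  posneg_model <- tryCatch(fit_posneg_latency_model(kept),
                           error = function(e) paste("not fitted:",
                                                     conditionMessage(e)))
  inter_model <- tryCatch(fit_intermediate_model(kept, speeds),
                          error = function(e) paste("not fitted:",
                                                    conditionMessage(e)))
  tukey <- if (inherits(inter_model, "jb_model_fit")) {
    tryCatch(tukey_hsd(inter_model), error = function(e) NULL)
  }

  report <- structure(list(
    conformance = conf,
    training = train_tab,
    training_summary = train_sum,
    choice_sessions = choice_tab,
    choice_trend = choice_trend,
    posneg_t_tests = posneg_tests,
    pessimism = pessimism,
    trajectories = trajectories,
    session_speeds = speeds,
    posneg_latency_model = posneg_model,
    intermediate_model = inter_model,
    tukey = tukey,
    options = opts
  ), class = "jb_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Internal: serialize a report to JSON + tidy CSVs.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(x) {
    if (inherits(x, "jb_model_fit")) {
      x$fit <- NULL; x$data <- NULL
      unclass(x)
    } else if (inherits(x, "jb_pessimism")) {
      list(subject_id = x$subject_id,
           mean_lat = as.list(x$mean_lat),
           std_lat = as.list(x$std_lat),
           pessimism_index = x$pessimism_index,
           n_trials = as.list(x$n_trials),
           scale = "raw_seconds")
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, strip)
    } else x
  }
  jsonlite::write_json(strip(unclass(report)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, na = "null")
  if (!is.null(report$trajectories)) {
    utils::write.csv(report$trajectories,
                     file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$choice_sessions)) {
    utils::write.csv(report$choice_sessions,
                     file.path(out_dir, "choice_sessions.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$training, file.path(out_dir, "training.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Replay the progression criteria over a recorded dataset
#'
#' Re-evaluates every training, choice and test progression decision from
#' the recorded trials, subject by subject, and flags any recorded phase
#' transition the criteria do not license -- e.g. leaving six-trial blocks
#' before three successive significant cumulative tests, or a test session
#' not preceded by a passed choice session.
#'
#' @param trials Trial table (canonical schema) or path.
#' @param protocol A [protocol_config()].
#' @return A list of class `jb_replay` with `decisions` (the rebuilt
#'   decision log across subjects) and `flags` (data frame of unlicensed
#'   transitions; zero rows when the record is consistent).
#' @export
cmd_replay_protocol <- function(trials, protocol = protocol_config()) {
  if (is.character(trials)) trials <- read_trials(trials, config = protocol)
  flags <- list()
  logs <- list()
  flag <- function(subject, session, expected, got, why) {
    flags[[length(flags) + 1L]] <<- data.frame(
      subject_id = subject, session_id = session, expected = expected,
      observed = got, reason = why, stringsAsFactors = FALSE)
  }
  for (s in unique(trials$subject_id)) {
    d <- trials[trials$subject_id == s, , drop = FALSE]
    state <- new_protocol_state(s, protocol)
    ords <- sort(unique(d$session_ordinal))
    for (o in ords) {
      sess <- d[d$session_ordinal == o, , drop = FALSE]
      sid <- sess$session_id[1]
      expected <- session_phase_for(state$phase)
      if (is.na(expected)) {
        flag(s, sid, "DONE", sess$phase[1],
             "sessions recorded after the protocol completed")
        break
      }
      if (sess$phase[1] != expected) {
        flag(s, sid, expected, sess$phase[1],
             sprintf("machine phase %s licenses a %s session%s",
                     state$phase, expected,
                     if (state$phase == "BLOCK6")
                       sprintf(" (minimum %d sessions, %d successive significant cumulative tests required)",
                               protocol$block6_min_sessions,
                               protocol$block6_required_successive)
                     else if (state$phase %in% c("CHOICE0", "CHOICE"))
                       sprintf(" (requires %d-of-%d POS-first choices)",
                               min_significant_choices(
                                 protocol$choice_session_trials,
                                 protocol$alpha),
                               protocol$choice_session_trials)
                     else ""))
        break
      }
      state <- advance_state(state, sess)
    }
    logs[[s]] <- state$log
    logs[[s]]$subject_id <- s
  }
  structure(list(
    decisions = do.call(rbind, c(logs, list(make.row.names = FALSE))),
    flags = if (length(flags)) do.call(rbind, flags) else
      data.frame(subject_id = character(0), session_id = character(0),
                 expected = character(0), observed = character(0),
                 reason = character(0), stringsAsFactors = FALSE)
  ), class = "jb_replay")
}

#' @export
print.jb_report <- function(x, ...) {
  cat("<jb_report>\n")
  cat("  conformance violations:", nrow(x$conformance), "\n")
  cat("  training summary: block6", round(x$training_summary$mean_block6_sessions, 2),
      "sessions, block3", round(x$training_summary$mean_block3_sessions, 2),
      "sessions, total trials",
      round(x$training_summary$mean_total_training_trials, 2), "\n")
  idx <- vapply(x$pessimism, function(p) {
    if (inherits(p, "jb_pessimism")) p$pessimism_index else NA_real_
  }, numeric(1))
  cat("  pessimism indices:",
      paste(names(idx), round(idx, 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.jb_replay <- function(x, ...) {
  cat("<jb_replay>", nrow(x$decisions), "decisions,",
      nrow(x$flags), "flag(s)\n")
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}
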