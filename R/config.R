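#' Stimulus set for the grey-scale discrimination
#'
#' The task uses five paper-cone stimuli identified by the percentage of grey
#' printed on them.  The positive stimulus (POS, 20% grey) is the only
#' rewarded one; the negative stimulus (NEG, 60% grey) and the three
#' intermediate probes (NP 30%, M 40%, NN 50%) are never rewarded.
#'
#' @return A data frame with columns `label`, `grey_pct` and `rewarded`,
#'   one row per stimulus, ordered from POS to NEG.
#' @export
#' @examples
#' stimulus_levels()
stimulus_levels <- function() {
  data.frame(
    label    = c("POS", "NP", "M", "NN", "NEG"),
    grey_pct = c(20L, 30L, 40L, 50L, 60L),
    rewarded = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname stimulus_levels
#' @param label Stimulus label(s), e.g. `"NP"`.
#' @return `grey_for_valence()` returns the integer percent grey for each
#'   label.
#' @export
grey_for_valence <- function(label) {
  lv <- stimulus_levels()
  idx <- match(label, lv$label)
  if (anyNA(idx)) {
    stop("unknown valence label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  lv$grey_pct[idx]
}

.intermediate_labels <- c("NP", "M", "NN")
.forced_labels <- c("POS", "NP", "M", "NN", "NEG")

#' Protocol configuration
#'
#' Bundles the fixed constants of the training and testing protocol: trial
#' counts per session, the composition of a test session, the response
#' cutoff and non-response code, and the parameters of the sequential
#' progression criteria.
#'
#' @param iti_s Inter-trial interval in seconds.
#' @param response_cutoff_s Maximum time allowed to touch a cone (seconds).
#' @param nonresponse_code_s Latency code recorded for a non-response during
#'   training (seconds); must exceed `response_cutoff_s`.
#' @param block6_size,block3_size Trials per block in the two block-training
#'   sub-phases.
#' @param training_session_trials,choice_session_trials,test_session_trials
#'   Trials per session in each phase.
#' @param test_counts Named integer vector giving the number of trials of
#'   each valence in a test session; must sum to `test_session_trials`.
#' @param alpha Significance level used by all progression criteria.
#' @param block6_min_sessions Minimum number of six-trial-block sessions.
#' @param block6_required_successive Number of successive sessions with a
#'   significant cumulative test required to leave the six-trial-block phase.
#' @param block3_min_sessions Minimum number of three-trial-block sessions.
#' @param n_test_sessions Number of test sessions per subject.
#' @param training_scale Scale on which the cumulative training t-test is
#'   run: `"raw"` (seconds, default) or `"reciprocal"` (1/latency).
#' @param t_variant Two-sample t-test variant used by the training
#'   criterion: `"welch"` (default) or `"pooled"`.
#'
#' @return A list of class `jb_protocol_config`.
#' @export
#' @examples
#' cfg <- protocol_config()
#' cfg$test_counts
protocol_config <- function(iti_s = 30,
                            response_cutoff_s = 60,
                            nonresponse_code_s = 61,
                            block6_size = 6L,
                            block3_size = 3L,
                            training_session_trials = 24L,
                            choice_session_trials = 24L,
                            test_session_trials = 25L,
                            test_counts = c(POS = 8L, NEG = 8L,
                                            NP = 3L, M = 3L, NN = 3L),
                            alpha = 0.05,
                            block6_min_sessions = 3L,
                            block6_required_successive = 3L,
                            block3_min_sessions = 1L,
                            n_test_sessions = 5L,
                            training_scale = c("raw", "reciprocal"),
                            t_variant = c("welch", "pooled")) {
  cfg <- list(
    iti_s = iti_s,
    response_cutoff_s = response_cutoff_s,
    nonresponse_code_s = nonresponse_code_s,
    block6_size = as.integer(block6_size),
    block3_size = as.integer(block3_size),
    training_session_trials = as.integer(training_session_trials),
    choice_session_trials = as.integer(choice_session_trials),
    test_session_trials = as.integer(test_session_trials),
    test_counts = test_counts,
    alpha = alpha,
    block6_min_sessions = as.integer(block6_min_sessions),
    block6_required_successive = as.integer(block6_required_successive),
    block3_min_sessions = as.integer(block3_min_sessions),
    n_test_sessions = as.integer(n_test_sessions),
    training_scale = match.arg(training_scale),
    t_variant = match.arg(t_variant)
  )
  class(cfg) <- "jb_protocol_config"
  validate_protocol_config(cfg)
  cfg
}

validate_protocol_config <- function(cfg) {
  counts <- c(cfg$iti_s, cfg$response_cutoff_s, cfg$nonresponse_code_s,
              cfg$block6_size, cfg$block3_size,
              cfg$training_session_trials, cfg$choice_session_trials,
              cfg$test_session_trials, cfg$block6_min_sessions,
              cfg$block6_required_successive, cfg$block3_min_sessions,
              cfg$n_test_sessions, cfg$test_counts)
  if (any(counts <= 0)) {
    stop("all protocol durations and counts must be strictly positive")
  }
  if (sum(cfg$test_counts) != cfg$test_session_trials) {
    stop("test_counts must sum to test_session_trials (",
         sum(cfg$test_counts), " != ", cfg$test_session_trials, ")")
  }
  if (!all(.forced_labels %in% names(cfg$test_counts))) {
    stop("test_counts must name all of POS, NP, M, NN, NEG")
  }
  if (cfg$nonresponse_code_s <= cfg$response_cutoff_s) {
    stop("nonresponse_code_s must exceed response_cutoff_s")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  invisible(cfg)
}
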