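#' Select the test trials used in analyses
#'
#' All test-phase analyses exclude trials on which the subject did not
#' touch the cone within the response cutoff; this removes variation due
#' to lapses of motivation or attention rather than judgment.  The
#' exclusion applies to every valence, POS and NEG included.
#'
#' @param trials Trial data frame (canonical schema).
#' @return The responded TEST-phase trials; the attribute `"excluded"`
#'   holds a per-valence table of excluded (non-responded) trial counts.
#' @export
filter_test_trials <- function(trials) {
  test <- trials[trials$phase == "TEST", , drop = FALSE]
  kept <- test[test$responded, , drop = FALSE]
  excl <- table(factor(test$valence[!test$responded],
                       levels = .forced_labels))
  attr(kept, "excluded") <- excl
  kept
}

#' Per-session speed covariate
#'
#' A subject's overall readiness to respond in a test session, measured as
#' the mean transformed latency over the responded POS and NEG trials of
#' that session (intermediate trials excluded).  Used as a covariate to
#' control for day-to-day motivation when analysing intermediate-cone
#' latencies.
#'
#' @param session_trials Trials of one test session.
#' @param scale `"reciprocal"` (default; the mean of 1/latency is a speed)
#'   or `"raw"` (mean seconds).
#' @return A list with `speed` and `n_used`.
#' @export
session_speed <- function(session_trials, scale = c("reciprocal", "raw")) {
  scale <- match.arg(scale)
  use <- session_trials$valence %in% c("POS", "NEG") & session_trials$responded
  lat <- session_trials$latency_s[use]
  if (!length(lat)) {
    stop("undefined speed: no responded POS/NEG trials in session")
  }
  val <- if (scale == "reciprocal") mean(reciprocal_transform(lat)) else mean(lat)
  list(speed = val, n_used = length(lat), scale = scale)
}

#' Standardize a latency against a subject's POS/NEG anchors
#'
#' Rescales a latency so that the subject's mean POS latency maps to 0 and
#' its mean NEG latency to 1: `(lat - mean_pos) / (mean_neg - mean_pos)`.
#'
#' @param lat Latency (or vector of latencies) in seconds.
#' @param mean_pos,mean_neg The subject's mean POS and NEG latencies;
#'   must differ.
#' @return Standardized latency value(s).
#' @export
standardize_latency <- function(lat, mean_pos, mean_neg) {
  if (mean_neg == mean_pos) {
    stop("degenerate discrimination: mean NEG latency equals mean POS latency")
  }
  (lat - mean_pos) / (mean_neg - mean_pos)
}

#' Pessimism index
#'
#' `(mean intermediate latency - mean POS latency) /
#'  (mean NEG latency - mean POS latency)`.
#'
#' The index is 0 when the subject responds to the ambiguous intermediate
#' cones as fast as to the rewarded POS cone (optimistic) and 1 when it
#' responds as slowly as to the unrewarded NEG cone (pessimistic).  Values
#' below 0 or above 1 are possible and are not clipped.
#'
#' @param mean_intermediate Mean latency over intermediate (NP/M/NN)
#'   trials, seconds.
#' @param mean_pos,mean_neg Mean POS and NEG latencies, seconds; must
#'   differ.
#' @return The dimensionless index.
#' @export
#' @examples
#' pessimism_index(4, 2, 6)   # 0.5
#' pessimism_index(1, 2, 6)   # -0.25
pessimism_index <- function(mean_intermediate, mean_pos, mean_neg) {
  standardize_latency(mean_intermediate, mean_pos, mean_neg)
}

#' Per-subject pessimism summary
#'
#' Pools a subject's responded test trials across the given sessions and
#' computes mean latencies by valence (raw seconds), standardized
#' latencies, and the pessimism index.  The intermediate mean is the
#' trial-weighted mean over all NP, M and NN trials pooled together
#' (default), not the mean of the three per-valence means; set
#' `intermediate_mean = "by_valence"` for the mean-of-means variant as a
#' sensitivity analysis.
#'
#' @param trials Trial data frame (canonical schema).
#' @param subject Subject id.
#' @param sessions Optional vector of `session_id`s to include (default:
#'   all of the subject's test sessions).
#' @param intermediate_mean `"pooled"` (default) or `"by_valence"`.
#' @return A list of class `jb_pessimism` with elements `subject_id`,
#'   `mean_lat` (named by valence), `std_lat`, `pessimism_index`,
#'   `n_trials`, `sessions_included` and `n_excluded`.
#' @export
subject_pessimism <- function(trials, subject, sessions = NULL,
                              intermediate_mean = c("pooled", "by_valence")) {
  intermediate_mean <- match.arg(intermediate_mean)
  kept <- filter_test_trials(trials[trials$subject_id == subject, ,
                                    drop = FALSE])
  excluded <- attr(kept, "excluded")
  if (!is.null(sessions)) {
    kept <- kept[kept$session_id %in% sessions, , drop = FALSE]
  }
  n_by <- table(factor(kept$valence, levels = .forced_labels))
  if (n_by[["POS"]] < 1 || n_by[["NEG"]] < 1) {
    missing <- names(n_by)[n_by == 0 & names(n_by) %in% c("POS", "NEG")]
    stop("insufficient data: no responded ", paste(missing, collapse = "/"),
         " test trials for subject ", subject)
  }
  if (sum(n_by[.intermediate_labels]) < 1) {
    stop("insufficient data: no responded intermediate (NP/M/NN) test trials",
         " for subject ", subject)
  }
  mean_lat <- tapply(kept$latency_s, factor(kept$valence,
                                            levels = .forced_labels), mean)
  m_pos <- mean_lat[["POS"]]; m_neg <- mean_lat[["NEG"]]
  inter <- kept$latency_s[kept$valence %in% .intermediate_labels]
  m_int <- if (intermediate_mean == "pooled") {
    mean(inter)
  } else {
    mean(mean_lat[.intermediate_labels], na.rm = TRUE)
  }
  res <- list(
    subject_id = subject,
    mean_lat = mean_lat,
    std_lat = standardize_latency(mean_lat, m_pos, m_neg),
    mean_intermediate = m_int,
    pessimism_index = pessimism_index(m_int, m_pos, m_neg),
    n_trials = n_by,
    sessions_included = unique(kept$session_id),
    n_excluded = excluded,
    intermediate_mean = intermediate_mean
  )
  class(res) <- "jb_pessimism"
  res
}

#' @export
print.jb_pessimism <- function(x, ...) {
  cat("<jb_pessimism>", x$subject_id,
      sprintf("| index = %.3f (%s intermediate mean)\n",
              x$pessimism_index, x$intermediate_mean))
  print(round(rbind(mean_latency_s = x$mean_lat, standardized = x$std_lat), 3))
  invisible(x)
}

#' Per-session and cumulative statistic trajectories
#'
#' For each test session `k` of a subject, computes three summary
#' statistics twice: once from session `k`'s trials alone
#' (`mode = "per_session"`) and once from all trials of sessions `1..k`
#' pooled (`mode = "cumulative"`).  The statistics are the speed to touch
#' POS and NEG cones, Cohen's d for the POS-NEG latency difference
#' (computed on `scale`), and the pessimism index (always on raw-second
#' means).  Tracking the cumulative column shows how many test sessions
#' are needed before the estimates stabilise.
#'
#' @inheritParams subject_pessimism
#' @param scale Scale for the speed and Cohen's d statistics:
#'   `"reciprocal"` (default) or `"raw"`.
#' @return A data frame with columns `subject_id`, `session_k`, `mode`,
#'   `speed`, `cohens_d_posneg`, `pessimism_index`.
#' @export
trajectory <- function(trials, subject, scale = c("reciprocal", "raw")) {
  scale <- match.arg(scale)
  kept <- filter_test_trials(trials[trials$subject_id == subject, ,
                                    drop = FALSE])
  ords <- sort(unique(kept$session_ordinal))
  if (!length(ords)) stop("no test sessions for subject ", subject)
  sess_ids <- vapply(ords, function(o) {
    unique(kept$session_id[kept$session_ordinal == o])[1]
  }, character(1))

  one <- function(sub, ids) {
    lat <- sub$latency_s
    posneg <- sub$valence %in% c("POS", "NEG")
    tl <- if (scale == "reciprocal") reciprocal_transform(lat) else lat
    pos <- tl[sub$valence == "POS"]; neg <- tl[sub$valence == "NEG"]
    d <- tryCatch(cohens_d(pos, neg)$d, error = function(e) NA_real_)
    pi <- tryCatch(
      subject_pessimism(trials, subject, sessions = ids)$pessimism_index,
      error = function(e) NA_real_)
    c(speed = mean(tl[posneg]), cohens_d_posneg = d, pessimism_index = pi)
  }

  rows <- lapply(seq_along(ords), function(k) {
    per <- one(kept[kept$session_ordinal == ords[k], , drop = FALSE],
               sess_ids[k])
    cum <- one(kept[kept$session_ordinal %in% ords[1:k], , drop = FALSE],
               sess_ids[1:k])
    data.frame(subject_id = subject, session_k = k,
               mode = c("per_session", "cumulative"),
               rbind(per, cum), row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- scale
  out
}
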