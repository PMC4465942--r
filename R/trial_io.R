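#' Canonical trial table schema
#'
#' One row per trial.  Columns:
#' `subject_id`, `session_id`, `session_ordinal` (integer ordering key for
#' sessions within a subject), `phase` (`BLOCK6`, `BLOCK3`, `CHOICE`,
#' `TEST`), `trial_index` (1-based within session), `trial_kind` (`forced`
#' or `choice`), `valence` (stimulus label, or `POSNEG` on choice trials),
#' `pos_side` (side of the POS cone, choice trials only), `side` (side of
#' the single cone, forced trials only), `responded` (logical),
#' `latency_s` (seconds to first touch, in (0, 60\]; empty on
#' non-response), `coded_latency_s` (`latency_s`, or 61 on non-response)
#' and `first_touch` (`POS`/`NEG`, responded choice trials only).
#'
#' @name trial-schema
#' @keywords internal
NULL

trial_columns <- c("subject_id", "session_id", "session_ordinal", "phase",
                   "trial_index", "trial_kind", "valence", "pos_side",
                   "side", "responded", "latency_s", "coded_latency_s",
                   "first_touch")

.phases <- c("BLOCK6", "BLOCK3", "CHOICE", "TEST")

#' Read a trial table from CSV
#'
#' Reads trial-level data in the canonical schema (see [write_trials()]),
#' optionally renaming columns of an external file first, validates every
#' record invariant, and returns the trials ordered by subject, session
#' ordinal and trial index.
#'
#' @param path CSV file path.
#' @param schema_map Optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(subject_id = "chimp", latency_s = "lat")`.  Unmapped canonical
#'   names are looked up directly.
#' @param config A [protocol_config()] (used for the censoring code and
#'   response cutoff).
#' @return A validated data frame of class `jb_trials`.
#' @export
read_trials <- function(path, schema_map = NULL, config = protocol_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!is.null(schema_map)) {
    for (canon in names(schema_map)) {
      src <- schema_map[[canon]]
      if (!src %in% names(raw)) {
        stop("schema error: mapped column '", src, "' (for '", canon,
             "') not present in file")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing <- setdiff(trial_columns, names(raw))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- raw[trial_columns]
  df$responded <- as.logical(df$responded)
  df$session_ordinal <- as.integer(df$session_ordinal)
  df$trial_index <- as.integer(df$trial_index)
  df$latency_s <- as.numeric(df$latency_s)
  df$coded_latency_s <- as.numeric(df$coded_latency_s)
  for (col in c("subject_id", "session_id", "phase", "trial_kind",
                "valence", "pos_side", "side", "first_touch")) {
    df[[col]] <- as.character(df[[col]])
  }
  df <- df[order(df$subject_id, df$session_ordinal, df$trial_index), ,
           drop = FALSE]
  rownames(df) <- NULL
  validate_trials(df, config = config)
  class(df) <- c("jb_trials", "data.frame")
  df
}

#' Validate trial records
#'
#' Enforces the per-record invariants of the canonical schema: known phase
#' and valence labels, the censoring rule (`responded = FALSE` iff
#' `coded_latency_s` equals the non-response code and `latency_s` is
#' missing), responded latencies within (0, cutoff\], and `first_touch`
#' recorded exactly on responded choice trials.  Errors cite the offending
#' row numbers.
#'
#' @param trials A trial data frame in the canonical schema.
#' @inheritParams read_trials
#' @return The trials, invisibly, if valid.
#' @export
validate_trials <- function(trials, config = protocol_config()) {
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      rows <- which(cond)
      stop("validation error (rows ",
           paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) ", ..." else "", "): ", what)
    }
  }
  bad_row(!trials$phase %in% .phases, "unknown phase label")
  bad_row(!trials$trial_kind %in% c("forced", "choice"), "unknown trial_kind")
  bad_row(trials$trial_kind == "choice" & trials$phase != "CHOICE",
          "choice trials must be in the CHOICE phase")
  forced <- trials$trial_kind == "forced"
  bad_row(forced & !trials$valence %in% .forced_labels,
          "unknown valence label on forced trial")
  bad_row(!forced & trials$valence != "POSNEG",
          "choice trials must have valence POSNEG")
  bad_row(!forced & !trials$pos_side %in% c("left", "right"),
          "choice trials need pos_side left/right")
  bad_row(is.na(trials$responded), "responded must be TRUE/FALSE")

  resp <- trials$responded
  bad_row(!resp & !is.na(trials$latency_s),
          "non-response rows must have empty latency_s")
  bad_row(!resp & trials$coded_latency_s != config$nonresponse_code_s,
          paste0("non-response rows must be coded ", config$nonresponse_code_s,
                 " s"))
  bad_row(resp & (is.na(trials$latency_s) | trials$latency_s <= 0 |
                    trials$latency_s > config$response_cutoff_s),
          paste0("responded latencies must lie in (0, ",
                 config$response_cutoff_s, "]"))
  bad_row(resp & abs(trials$coded_latency_s - trials$latency_s) > 1e-9,
          "responded rows must have coded_latency_s equal to latency_s")
  bad_row(resp & !forced & !trials$first_touch %in% c("POS", "NEG"),
          "responded choice trials must record first_touch POS/NEG")
  bad_row(forced & !is.na(trials$first_touch),
          "first_touch is defined only on choice trials")
  invisible(trials)
}

#' Write a trial table to CSV
#'
#' Writes trials in the canonical schema with a deterministic column order;
#' missing latencies (non-responses) become empty fields.  A `planned`
#' column, if present, is carried through.
#'
#' @param trials Trial data frame (canonical schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c(trial_columns, intersect("planned", names(trials)))
  if (nrow(trials) > 0) {
    missing <- setdiff(trial_columns, names(trials))
    if (length(missing)) {
      stop("cannot write: missing column(s) ", paste(missing, collapse = ", "))
    }
    out <- trials[cols]
  } else {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Check a dataset against the protocol's structural rules
#'
#' Produces a report of protocol-conformance violations: wrong per-session
#' trial counts, non-consecutive trial indices, wrong test-session
#' composition or sides, unbalanced sides where balance is required
#' (within six-trial blocks, per valence within three-trial-block and
#' choice sessions), a test session not starting with POS/NEG, or adjacent
#' intermediate test trials.  Violations are report rows, not errors; an
#' empty report means the data conform.
#'
#' @param trials Trial data frame (canonical schema).
#' @inheritParams read_trials
#' @return A data frame with columns `subject_id`, `session_id`, `rule`
#'   and `detail`; zero rows when the data conform.
#' @export
validate_protocol_conformance <- function(trials, config = protocol_config()) {
  viol <- list()
  note <- function(subject, session, rule, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      subject_id = subject, session_id = session, rule = rule,
      detail = detail, stringsAsFactors = FALSE)
  }
  expected_n <- c(BLOCK6 = config$training_session_trials,
                  BLOCK3 = config$training_session_trials,
                  CHOICE = config$choice_session_trials,
                  TEST = config$test_session_trials)

  for (key in split(seq_len(nrow(trials)),
                    paste(trials$subject_id, trials$session_id, sep = "\r"))) {
    s <- trials[key, , drop = FALSE]
    s <- s[order(s$trial_index), , drop = FALSE]
    subj <- s$subject_id[1]; sess <- s$session_id[1]; phase <- s$phase[1]

    if (length(unique(s$phase)) > 1) {
      note(subj, sess, "single_phase", "session mixes phases")
      next
    }
    if (nrow(s) != expected_n[[phase]]) {
      note(subj, sess, "session_trials",
           sprintf("%s session has %d trials, expected %d",
                   phase, nrow(s), expected_n[[phase]]))
    }
    if (!identical(s$trial_index, seq_len(nrow(s)))) {
      note(subj, sess, "trial_index", "trial_index not consecutive from 1")
    }

    if (phase == "TEST") {
      counts <- table(factor(s$valence, levels = names(config$test_counts)))
      if (!all(counts == config$test_counts[names(counts)])) {
        note(subj, sess, "test_counts",
             paste0("composition ", paste(names(counts), counts,
                                          sep = "=", collapse = " "),
                    "; expected ", paste(names(config$test_counts),
                                         config$test_counts,
                                         sep = "=", collapse = " ")))
      }
      if (any(s$side != "right")) {
        note(subj, sess, "test_side", "test cones must all be on the right")
      }
      if (!(s$valence[1] %in% c("POS", "NEG"))) {
        note(subj, sess, "test_first_trial",
             "test session must start with POS or NEG")
      }
      inter <- s$valence %in% .intermediate_labels
      if (any(inter[-1] & inter[-length(inter)])) {
        note(subj, sess, "test_interspersion",
             "two intermediate trials are adjacent")
      }
    } else if (phase == "CHOICE") {
      n_left <- sum(s$pos_side == "left", na.rm = TRUE)
      if (n_left != nrow(s) / 2) {
        note(subj, sess, "choice_side_balance",
             sprintf("POS on left %d times of %d (expected %g)",
                     n_left, nrow(s), nrow(s) / 2))
      }
    } else if (phase == "BLOCK6") {
      blocks <- split(seq_len(nrow(s)),
                      (seq_len(nrow(s)) - 1) %/% config$block6_size)
      for (b in blocks) {
        if (length(unique(s$valence[b])) > 1) {
          note(subj, sess, "block_valence", "mixed valences within a block")
        }
        if (sum(s$side[b] == "left") != length(b) / 2) {
          note(subj, sess, "block_side_balance",
               "sides unbalanced within a six-trial block")
        }
      }
    } else if (phase == "BLOCK3") {
      for (v in c("POS", "NEG")) {
        idx <- s$valence == v
        if (sum(idx) && sum(s$side[idx] == "left") != sum(idx) / 2) {
          note(subj, sess, "block_side_balance",
               paste0(v, " sides unbalanced within session"))
        }
      }
    }
  }
  if (length(viol)) {
    do.call(rbind, viol)
  } else {
    data.frame(subject_id = character(0), session_id = character(0),
               rule = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  }
}
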