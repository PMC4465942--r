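#' Session schedules
#'
#' @description
#' Generators for the four session types of the protocol.  Each returns a
#' data frame of planned trials (class `jb_schedule`, with the phase stored
#' in attribute `"phase"`) with columns:
#'
#' * `trial_index` -- 1-based position within the session,
#' * `valence` -- stimulus label, or `"POSNEG"` for choice trials,
#' * `side` -- side of the single cone on forced trials (`NA` for choice),
#' * `pos_side` -- side of the POS cone on choice trials (`NA` otherwise),
#' * `block` -- block number within block-training sessions (`NA` otherwise),
#' * `break_after` -- `TRUE` where a scheduled break follows the trial.
#'
#' Schedules are pure functions of their arguments: the same
#' `(block_size, session_ordinal, seed)` always yields the same schedule.
#' With `seed = NULL` the current RNG stream is consumed instead, which is
#' what the simulator uses.
#'
#' @details
#' Block-training sessions (`make_block_schedule()`) present forced trials
#' in alternating same-valence blocks.  With `block_size = 6` a session is
#' 4 blocks (2 POS, 2 NEG, 24 trials) and each side is used exactly 3 times
#' within every block.  With `block_size = 3` a session is 8 blocks (4 per
#' valence) and each valence appears exactly 6 times per side over the
#' session (per-block balance is impossible with an odd block size).  The
#' first-ever session starts with a POS block; thereafter the starting
#' valence alternates with `session_ordinal`.
#'
#' Choice sessions (`make_choice_schedule()`) are 24 trials with POS and
#' NEG presented simultaneously; the POS cone is on each side exactly 12
#' times, in seeded-pseudorandom order, with a break after trial 12.
#'
#' Test sessions (`make_test_schedule()`) are 25 forced trials -- 8 POS, 8
#' NEG and 3 each of NP, M and NN -- all presented on the right-hand side
#' to remove side-bias variance.  Orders are drawn by rejection sampling
#' until (i) the first trial is POS or NEG, (ii) no two intermediate trials
#' are adjacent, and (iii) POS and NEG counts differ by at most 2 within
#' each half of the session (split at the break after trial 13).  This is
#' the package's concrete reading of "approximately evenly distributed"
#' with "intermediate trials interspersed".
#'
#' @param block_size 6 or 3.
#' @param session_ordinal 1-based index of the session within block
#'   training, used to alternate the starting valence.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param config A [protocol_config()].
#' @return A `jb_schedule` data frame (see Description).
#' @export
#' @examples
#' s <- make_block_schedule(6, session_ordinal = 1, seed = 1)
#' table(s$valence, s$side)
make_block_schedule <- function(block_size, session_ordinal, seed = NULL,
                                config = protocol_config()) {
  if (!(block_size %in% c(config$block6_size, config$block3_size))) {
    stop("block_size must be ", config$block6_size, " or ", config$block3_size)
  }
  if (session_ordinal < 1) stop("session_ordinal must be >= 1")
  n_trials <- config$training_session_trials
  n_blocks <- n_trials / block_size
  start <- if (session_ordinal %% 2 == 1) "POS" else "NEG"
  other <- setdiff(c("POS", "NEG"), start)
  block_val <- rep(c(start, other), length.out = n_blocks)
  valence <- rep(block_val, each = block_size)
  block <- rep(seq_len(n_blocks), each = block_size)

  side <- with_seed(seed, {
    if (block_size %% 2 == 0) {
      # equal sides within every block
      unlist(lapply(seq_len(n_blocks), function(i) {
        sample(rep(c("left", "right"), block_size / 2))
      }))
    } else {
      # odd block size: balance each valence's sides over the whole session
      out <- character(n_trials)
      for (v in c("POS", "NEG")) {
        idx <- which(valence == v)
        out[idx] <- sample(rep(c("left", "right"), length(idx) / 2))
      }
      out
    }
  })

  sched <- data.frame(
    trial_index = seq_len(n_trials),
    valence = valence,
    side = side,
    pos_side = NA_character_,
    block = block,
    break_after = c(diff(block) != 0, FALSE),
    stringsAsFactors = FALSE
  )
  structure(sched, class = c("jb_schedule", "data.frame"),
            phase = if (block_size == config$block6_size) "BLOCK6" else "BLOCK3")
}

#' @rdname make_block_schedule
#' @export
make_choice_schedule <- function(seed = NULL, config = protocol_config()) {
  n <- config$choice_session_trials
  pos_side <- with_seed(seed, sample(rep(c("left", "right"), n / 2)))
  sched <- data.frame(
    trial_index = seq_len(n),
    valence = "POSNEG",
    side = NA_character_,
    pos_side = pos_side,
    block = NA_integer_,
    break_after = seq_len(n) == n / 2,
    stringsAsFactors = FALSE
  )
  structure(sched, class = c("jb_schedule", "data.frame"), phase = "CHOICE")
}

#' @rdname make_block_schedule
#' @export
make_test_schedule <- function(seed = NULL, config = protocol_config()) {
  counts <- config$test_counts
  pool <- rep(names(counts), counts)
  n <- config$test_session_trials
  break_at <- 13L
  half1 <- seq_len(break_at)

  draw <- function() {
    for (i in seq_len(100000L)) {
      ord <- sample(pool)
      if (!(ord[1] %in% c("POS", "NEG"))) next
      inter <- ord %in% .intermediate_labels
      if (any(inter[-1] & inter[-n])) next
      d1 <- abs(sum(ord[half1] == "POS") - sum(ord[half1] == "NEG"))
      d2 <- abs(sum(ord[-half1] == "POS") - sum(ord[-half1] == "NEG"))
      if (d1 > 2 || d2 > 2) next
      return(ord)
    }
    stop("failed to draw a conformant test order")  # nocov
  }
  ord <- with_seed(seed, draw())

  sched <- data.frame(
    trial_index = seq_len(n),
    valence = ord,
    side = "right",
    pos_side = NA_character_,
    block = NA_integer_,
    break_after = seq_len(n) == break_at,
    stringsAsFactors = FALSE
  )
  structure(sched, class = c("jb_schedule", "data.frame"), phase = "TEST")
}

#' Serialize a schedule as planned trials
#'
#' Converts a schedule into the canonical trial table layout (see
#' [write_trials()]) with observation fields empty and a `planned` flag set,
#' so planned sessions can be written next to observed ones.
#'
#' @param schedule A `jb_schedule`.
#' @param subject_id,session_id,session_ordinal Identifiers for the planned
#'   session.
#' @return A data frame in the canonical trial schema plus a `planned`
#'   column.
#' @export
schedule_to_trials <- function(schedule, subject_id, session_id,
                               session_ordinal = 1L) {
  phase <- attr(schedule, "phase")
  data.frame(
    subject_id = subject_id,
    session_id = session_id,
    session_ordinal = as.integer(session_ordinal),
    phase = phase,
    trial_index = schedule$trial_index,
    trial_kind = if (phase == "CHOICE") "choice" else "forced",
    valence = schedule$valence,
    pos_side = schedule$pos_side,
    side = schedule$side,
    responded = NA,
    latency_s = NA_real_,
    coded_latency_s = NA_real_,
    first_touch = NA_character_,
    planned = TRUE,
    stringsAsFactors = FALSE
  )
}
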