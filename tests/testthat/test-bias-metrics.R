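test_that("test-trial filtering drops exactly the non-responses", {
  ts <- test_session(c(POS = 2, NP = 3, M = 4, NN = 5, NEG = 6),
                     nonrespond_idx = c(1, 5, 9))
  kept <- filter_test_trials(ts)
  expect_equal(nrow(kept), 22)
  expect_true(all(kept$responded))
  expect_equal(sum(attr(kept, "excluded")), 3)
  # all responded: everything kept
  ts2 <- test_session(c(POS = 2, NP = 3, M = 4, NN = 5, NEG = 6))
  expect_equal(nrow(filter_test_trials(ts2)), 25)
  expect_equal(nrow(filter_test_trials(ts2[0, ])), 0)
  # training trials are never part of the test analyses
  expect_equal(nrow(filter_test_trials(choice_session(20))), 0)
})

test_that("session speed averages transformed responded POS/NEG latencies only", {
  ts <- test_session(c(POS = 2, NP = 9, M = 9, NN = 9, NEG = 2))
  expect_equal(session_speed(ts)$speed, 0.5)
  expect_equal(session_speed(ts, scale = "raw")$speed, 2)
  # latencies 1 and 4 -> mean of 1 and 0.25
  ts$latency_s[ts$valence == "POS"] <- 1
  ts$latency_s[ts$valence == "NEG"] <- 4
  expect_equal(session_speed(ts)$speed, 0.625)
  # non-responses are dropped before averaging
  idx <- which(ts$valence == "NEG")
  ts$responded[idx[1]] <- FALSE
  ts$latency_s[idx[1]] <- NA; ts$coded_latency_s[idx[1]] <- 61
  expect_equal(session_speed(ts)$n_used, 15)
  only_probe <- ts[ts$valence %in% c("NP", "M", "NN"), ]
  expect_error(session_speed(only_probe), "undefined speed")
})

test_that("standardized latency anchors POS at 0 and NEG at 1", {
  expect_equal(standardize_latency(2, 2, 6), 0)
  expect_equal(standardize_latency(6, 2, 6), 1)
  expect_equal(standardize_latency(4, 2, 6), 0.5)
  expect_error(standardize_latency(3, 2, 2), "degenerate")
})

test_that("pessimism index follows its defining formula, unclipped", {
  expect_equal(pessimism_index(4, 2, 6), 0.5)
  expect_equal(pessimism_index(1, 2, 6), -0.25)
  expect_equal(pessimism_index(2, 2, 6), 0)
  expect_equal(pessimism_index(6, 2, 6), 1)
  expect_equal(pessimism_index(8, 2, 6), 1.5)
})

test_that("subject summary pools trials (trial-weighted) across sessions", {
  trials <- rbind(
    test_session(c(POS = 2, NP = 3, M = 4, NN = 5, NEG = 6), ord = 1),
    test_session(c(POS = 2, NP = 3, M = 4, NN = 5, NEG = 6), ord = 2)
  )
  ps <- subject_pessimism(trials, "A")
  expect_equal(unname(ps$mean_lat["POS"]), 2)
  expect_equal(unname(ps$std_lat["POS"]), 0)
  expect_equal(unname(ps$std_lat["NEG"]), 1)
  expect_equal(ps$pessimism_index, 0.5)  # equal NP/M/NN counts: mean is 4 s
  # trial-weighted vs mean-of-means: knock out two NN trials
  tr2 <- trials
  nn <- which(tr2$valence == "NN")
  tr2 <- tr2[-nn[1:4], ]
  tr2 <- tr2[order(tr2$session_ordinal, tr2$trial_index), ]
  pw <- subject_pessimism(tr2, "A")
  mm <- subject_pessimism(tr2, "A", intermediate_mean = "by_valence")
  expect_equal(pw$mean_intermediate,
               mean(tr2$latency_s[tr2$valence %in% c("NP", "M", "NN")]))
  expect_equal(mm$mean_intermediate, mean(c(3, 4, 5)))
  expect_true(pw$mean_intermediate < mm$mean_intermediate)
  # single-session input equals the cumulative summary at k = 1
  s1 <- subject_pessimism(trials, "A", sessions = "A_001")
  expect_equal(s1$pessimism_index,
               subject_pessimism(trials[trials$session_ordinal == 1, ],
                                 "A")$pessimism_index)
  # a missing valence class is an explicit insufficiency
  no_int <- trials[!trials$valence %in% c("NP", "M", "NN"), ]
  expect_error(subject_pessimism(no_int, "A"), "intermediate")
})

test_that("index and standardized latencies are invariant under affine latency maps", {
  base <- rbind(
    test_session(c(POS = 2.2, NP = 3.1, M = 4.4, NN = 5.3, NEG = 6.1), ord = 1),
    test_session(c(POS = 2.0, NP = 3.3, M = 4.1, NN = 5.6, NEG = 6.4), ord = 2)
  )
  p0 <- subject_pessimism(base, "A")
  for (a in c(0.1, 1, 10)) {
    for (b in c(0, 5)) {
      tr <- base
      tr$latency_s <- a * tr$latency_s + b
      tr$coded_latency_s <- tr$latency_s
      p1 <- subject_pessimism(tr, "A")
      expect_equal(p1$pessimism_index, p0$pessimism_index, tolerance = 1e-12)
      expect_equal(p1$std_lat, p0$std_lat, tolerance = 1e-12)
    }
  }
})

test_that("trajectories: cumulative points equal pooled recomputation; K=1 modes agree", {
  sim <- simulate_subject(quiet_params(0.6), seed = 31)
  tr <- sim$trials
  traj <- trajectory(tr, "sim")
  expect_equal(nrow(traj), 10)  # 5 sessions x 2 modes
  cum5 <- traj[traj$mode == "cumulative" & traj$session_k == 5, ]
  expect_equal(cum5$pessimism_index,
               subject_pessimism(tr, "sim")$pessimism_index)
  # associativity oracle: cumulative k = statistic on concatenated sessions 1..k
  kept <- filter_test_trials(tr)
  ords <- sort(unique(kept$session_ordinal))
  for (k in seq_along(ords)) {
    sub <- kept[kept$session_ordinal %in% ords[1:k], ]
    tl <- 1 / sub$latency_s
    expect_equal(
      traj$speed[traj$mode == "cumulative" & traj$session_k == k],
      mean(tl[sub$valence %in% c("POS", "NEG")]))
    expect_equal(
      traj$cohens_d_posneg[traj$mode == "cumulative" & traj$session_k == k],
      cohens_d(tl[sub$valence == "POS"], tl[sub$valence == "NEG"])$d)
  }
  # per-session and cumulative coincide at k = 1
  expect_equal(traj[traj$session_k == 1 & traj$mode == "per_session",
                    c("speed", "cohens_d_posneg", "pessimism_index")],
               traj[traj$session_k == 1 & traj$mode == "cumulative",
                    c("speed", "cohens_d_posneg", "pessimism_index")],
               ignore_attr = TRUE)
})

test_that("stable subjects keep their cumulative pessimism rank from session 2 on", {
  sims <- lapply(c(0.15, 0.5, 0.85), function(p) {
    simulate_subject(quiet_params(p), seed = round(1e4 * p))
  })
  ranks <- sapply(1:5, function(k) {
    idx <- vapply(sims, function(s) {
      tr <- trajectory(s$trials, "sim")
      tr$pessimism_index[tr$mode == "cumulative" & tr$session_k == k]
    }, numeric(1))
    order(idx)
  })
  for (k in 2:5) expect_equal(ranks[, k], ranks[, 2])
  expect_equal(ranks[, 2], 1:3)
})
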