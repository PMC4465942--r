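test_that("expected latency interpolates between the trained anchors", {
  p <- behavior_params(mu_log_lat = log(3), delta = 4, p_true = 0,
                       gradient = 0)
  learned <- learning_state(1e9, p)
  expect_equal(expected_latency("POS", p, learned), 3)
  expect_equal(expected_latency("NEG", p, learned), 7)
  # p_true = 0, no gradient: intermediates behave like POS
  expect_equal(expected_latency(c("NP", "M", "NN"), p, learned), rep(3, 3))
  # p_true = 1: intermediates behave like NEG
  p1 <- behavior_params(p_true = 1, gradient = 0, mu_log_lat = log(3),
                        delta = 4)
  expect_equal(expected_latency(c("NP", "M", "NN"), p1, learned), rep(7, 3))
  # no discrimination before any training
  naive <- learning_state(0, p)
  expect_equal(expected_latency("NEG", p, naive),
               expected_latency("POS", p, naive))
  # the mean of the three intermediate expectations recovers p_true
  p2 <- behavior_params(p_true = 0.4, gradient = 0.2, mu_log_lat = log(3),
                        delta = 5)
  e <- expected_latency(c("NP", "M", "NN"), p2, learned)
  expect_equal(mean(e), 3 + 0.4 * (expected_latency("NEG", p2, learned) - 3))
})

test_that("discrimination fraction is non-decreasing in experience", {
  p <- behavior_params(tau = 50)
  fr <- vapply(seq(0, 500, by = 10),
               function(n) learning_state(n, p)$discrimination_frac,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr < 1))
})

test_that("trial draws respect censoring and are seed-deterministic", {
  p <- behavior_params(sigma_trial = 0, sigma_sess = 0, p_nonresponse = 0)
  st <- learning_state(1e9, p)
  set.seed(1)
  tr <- draw_trial("POS", p, st)
  expect_true(tr$responded)
  expect_equal(tr$latency_s, exp(p$mu_log_lat))
  # expectation beyond the cutoff is always censored and coded 61
  pslow <- behavior_params(mu_log_lat = log(120), sigma_trial = 0,
                           p_nonresponse = 0)
  tr2 <- draw_trial("POS", pslow, learning_state(0, pslow))
  expect_false(tr2$responded)
  expect_equal(tr2$coded_latency_s, 61)
  # same seed, same draw
  set.seed(33); a <- draw_trial("M", behavior_params(), st)
  set.seed(33); b <- draw_trial("M", behavior_params(), st)
  expect_identical(a, b)
})

test_that("no simulated responded latency exceeds the cutoff; non-responses are coded 61", {
  study <- generate_study(n_subjects = 3, seed = 23)
  tr <- study$trials
  expect_true(all(tr$latency_s[tr$responded] <= 60))
  expect_true(all(tr$coded_latency_s[!tr$responded] == 61))
  expect_true(all(is.na(tr$latency_s[!tr$responded])))
})

test_that("choice preference starts at chance and strengthens with learning", {
  p <- behavior_params(beta_choice = 5, tau = 50)
  expect_equal(plogis(p$beta_choice *
                        learning_state(0, p)$discrimination_frac), 0.5)
  set.seed(2)
  frac_pos <- vapply(c(0, 25, 100, 400), function(n) {
    st <- learning_state(n, p)
    mean(replicate(400, draw_choice(p, st)) == "POS")
  }, numeric(1))
  expect_true(all(diff(frac_pos) > -0.05))
  expect_gt(frac_pos[4], 0.9)
  # while acquisition is still incomplete (large tau), the preference
  # strengthens across choice sessions: positive slope in the mixed model
  # over a batch of simulated subjects
  rows <- list()
  for (i in 1:12) {
    sim <- simulate_subject(behavior_params(tau = 300, beta_choice = 4),
                            seed = 9100 + i)
    ch <- sim$trials[sim$trials$phase == "CHOICE", ]
    ords <- sort(unique(ch$session_ordinal))
    for (j in seq_along(ords)) {
      cs <- ch[ch$session_ordinal == ords[j], ]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = paste0("S", i), session_number = j - 1L,
        prop_pos = sum(cs$first_touch == "POS", na.rm = TRUE) / nrow(cs))
    }
  }
  trend <- fit_choice_trend(do.call(rbind, rows))
  slope <- trend$coefficients$estimate[
    trend$coefficients$term == "session_number"]
  expect_gt(slope, 0)
})

test_that("an easy discrimination finishes six-trial blocks in the minimum 3 sessions", {
  p <- behavior_params(delta = 20, tau = 5, sigma_trial = 0.05,
                       sigma_sess = 0.02, p_nonresponse = 0)
  sims <- lapply(1:10, function(i) {
    simulate_subject(p, seed = 700 + i, stop_after = "BLOCK6",
                     session_cap = 10)
  })
  n6 <- vapply(sims, function(s) sum(s$state$log$phase == "BLOCK6"),
               numeric(1))
  expect_true(all(n6 == 3))
})

test_that("with no discrimination the protocol stalls at the session cap", {
  flagged <- vapply(1:40, function(i) {
    sim <- simulate_subject(behavior_params(delta = 0), seed = 800 + i,
                            session_cap = 12)
    sim$capped
  }, logical(1))
  expect_gte(mean(flagged), 0.85)
})

test_that("study generation is deterministic and emulates the deposited structure", {
  s1 <- generate_study(n_subjects = 3, seed = 5)
  s2 <- generate_study(n_subjects = 3, seed = 5)
  expect_identical(s1$trials, s2$trials)
  tst <- s1$trials[s1$trials$phase == "TEST", ]
  per <- table(tst$subject_id, tst$valence)
  for (s in rownames(per)) {
    expect_equal(unclass(per[s, c("POS", "NEG", "NP", "M", "NN")]),
                 c(POS = 40, NEG = 40, NP = 15, M = 15, NN = 15),
                 ignore_attr = TRUE)
    expect_equal(sum(tst$subject_id == s), 125)
  }
  # ground truth sidecar aligns with the subjects
  expect_equal(s1$truth$subject_id, c("S1", "S2", "S3"))
  expect_equal(s1$truth$p_true, c(0.2, 0.5, 0.8))
})

test_that("recovered pessimism indices preserve the generating order", {
  study <- generate_study(
    n_subjects = 3,
    params = lapply(c(0.2, 0.5, 0.8), quiet_params),
    seed = 11)
  idx <- vapply(c("S1", "S2", "S3"), function(s) {
    subject_pessimism(study$trials, s)$pessimism_index
  }, numeric(1))
  expect_equal(order(idx), 1:3)
})
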