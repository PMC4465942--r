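# Shared fixture: responded POS/NEG test trials for several subjects and
# sessions with controllable per-(subject, session, valence) latency means.
make_posneg_data <- function(n_subj = 3, n_sess = 5, n_per = 8,
                             mean_fun = function(s, k, v) 3,
                             sd = 0.3, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) {
    for (k in seq_len(n_sess)) {
      for (v in c("POS", "NEG")) {
        lat <- pmin(pmax(rnorm(n_per, mean_fun(s, k, v), sd), 0.2), 60)
        for (i in seq_along(lat)) {
          rows[[length(rows) + 1L]] <- trial_row(
            subject = paste0("S", s), session = sprintf("S%d_%02d", s, k),
            ord = k, idx = length(rows) %% 25 + 1, valence = v,
            latency = lat[i])
        }
      }
    }
  }
  do.call(rbind, rows)
}

test_that("fixed-effect fits agree with a normal-equations oracle", {
  d <- make_posneg_data(n_subj = 2, n_sess = 2, n_per = 4, seed = 4)
  fit <- fit_posneg_latency_model(d)
  X <- model.matrix(~ factor(subject_id) * factor(session_ordinal), d)
  y <- 1 / d$latency_s
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients$estimate), drop(beta),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$n_obs, nrow(d))
  expect_equal(fit$response_scale, "reciprocal_latency")
})

test_that("subject-by-session interaction is detected when and only when present", {
  # distinct per-cell means: interaction should be overwhelming
  f_strong <- function(s, k, v) 2 + 1.5 * ((s + k) %% 3)
  d1 <- make_posneg_data(mean_fun = f_strong, sd = 0.2, seed = 7)
  fit1 <- fit_posneg_latency_model(d1)
  p1 <- fit1$anova$p[fit1$anova$term == "chimp:session"]
  expect_lt(p1, 0.01)

  # null: interaction p exceeds alpha in >= 90% of replicates
  pvals <- vapply(1:100, function(r) {
    d0 <- make_posneg_data(n_subj = 3, n_sess = 3, n_per = 5, seed = 100 + r)
    f <- fit_posneg_latency_model(d0)
    f$anova$p[f$anova$term == "chimp:session"]
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
  # and p-values are roughly uniform under the null
  expect_lt(suppressWarnings(
    stats::ks.test(pvals, "punif")$statistic), 0.15)

  expect_error(fit_posneg_latency_model(
    make_posneg_data(n_subj = 1, seed = 1)), "estimability")
})

# Intermediate-trial fixture with per-subject standardized levels.
make_intermediate_data <- function(levels_by_subj, n_sess = 5, sd = 0.2,
                                   seed = 1, speed_jitter = 0.2) {
  set.seed(seed)
  pos <- 2; neg <- 8
  rows <- list(); speeds <- list()
  for (s in seq_along(levels_by_subj)) {
    for (k in seq_len(n_sess)) {
      day <- exp(rnorm(1, 0, speed_jitter))
      for (v in c("NP", "M", "NN")) {
        mu <- (pos + levels_by_subj[s] * (neg - pos)) * day
        for (i in 1:3) {
          lat <- min(max(rnorm(1, mu, sd), 0.2), 60)
          rows[[length(rows) + 1L]] <- trial_row(
            subject = paste0("S", s), session = sprintf("S%d_%02d", s, k),
            ord = k, idx = length(rows) %% 25 + 1, valence = v, latency = lat)
        }
      }
      speeds[[length(speeds) + 1L]] <- data.frame(
        subject_id = paste0("S", s), session_id = sprintf("S%d_%02d", s, k),
        speed = 1 / (day * (pos + neg) / 2), stringsAsFactors = FALSE)
    }
  }
  list(trials = do.call(rbind, rows), speeds = do.call(rbind, speeds))
}

test_that("intermediate-cone model separates subjects with different levels", {
  strong <- make_intermediate_data(c(0.1, 0.9), seed = 3)
  f1 <- fit_intermediate_model(strong$trials, strong$speeds)
  expect_lt(f1$anova$p[f1$anova$term == "chimp"], 0.01)

  pvals <- vapply(1:100, function(r) {
    nul <- make_intermediate_data(c(0.5, 0.5, 0.5), seed = 200 + r)
    f <- fit_intermediate_model(nul$trials, nul$speeds)
    f$anova$p[f$anova$term == "chimp"]
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)

  # constant covariate: dropped and flagged rather than breaking the fit
  cst <- make_intermediate_data(c(0.2, 0.8), seed = 5)
  cst$speeds$speed <- 0.4
  f2 <- fit_intermediate_model(cst$trials, cst$speeds)
  expect_true(f2$degenerate_speed)
  expect_false("speed" %in% f2$anova$term)

  # unmatched session speeds are a linkage error
  expect_error(fit_intermediate_model(strong$trials, strong$speeds[-1, ]),
               "linkage")
})

test_that("tukey_hsd reproduces stats::TukeyHSD on a balanced one-way design", {
  set.seed(9)
  d <- data.frame(chimp = factor(rep(c("a", "b", "c"), each = 40)),
                  y = rnorm(120, rep(c(0, 0, 1), each = 40), 0.1))
  fit <- lm(y ~ chimp, data = d)
  mine <- tukey_hsd(fit)
  ref <- stats::TukeyHSD(stats::aov(y ~ chimp, data = d))$chimp
  expect_equal(mine$diff, unname(ref[, "diff"]), tolerance = 1e-9)
  expect_equal(mine$ci_low, unname(ref[, "lwr"]), tolerance = 1e-9)
  expect_equal(mine$ci_high, unname(ref[, "upr"]), tolerance = 1e-9)
  expect_equal(mine$p_adjusted, unname(ref[, "p adj"]), tolerance = 1e-7)
  # only pairs involving the offset group are significant
  sig <- mine$p_adjusted < 0.05
  expect_equal(sig, grepl("c", mine$pair))
  # family-wise correction never makes a contrast more significant
  praw <- with(d, pairwise.t.test(y, chimp, p.adjust.method = "none"))$p.value
  expect_gte(mine$p_adjusted[mine$pair == "b-a"], praw["b", "a"])
})

test_that("tukey_hsd on identical groups returns a null difference", {
  d <- data.frame(chimp = factor(rep(c("a", "b"), each = 10)),
                  y = rep(c(1, 1.0000001), 10))
  fit <- lm(y ~ chimp, data = d)
  res <- tukey_hsd(fit)
  expect_lt(abs(res$diff), 1e-7)
  expect_gt(res$p_adjusted, 0.99)
})

test_that("tukey_hsd adjusts subject means to the covariate mean", {
  dat <- make_intermediate_data(c(0.2, 0.2, 0.8), seed = 11,
                                speed_jitter = 0.05)
  fit <- fit_intermediate_model(dat$trials, dat$speeds)
  res <- tukey_hsd(fit)
  expect_equal(nrow(res), 3)
  expect_true(all(res$ci_low <= res$diff & res$diff <= res$ci_high))
  # the genuinely different subject dominates the contrasts; the like
  # pair's adjusted difference is an order of magnitude smaller
  expect_lt(res$p_adjusted[res$pair == "S3-S1"], 0.001)
  expect_lt(res$p_adjusted[res$pair == "S3-S2"], 0.001)
  d12 <- abs(res$diff[res$pair == "S2-S1"])
  expect_lt(d12, 0.2 * abs(res$diff[res$pair == "S3-S1"]))
})

test_that("choice-trend mixed model recovers a generating slope and its LRT is a deviance change", {
  make_choice_data <- function(slope, seed, n_subj = 20, n_sess = 6) {
    set.seed(seed)
    d <- expand.grid(subject_id = paste0("S", seq_len(n_subj)),
                     session_number = seq_len(n_sess) - 1L)
    u <- rnorm(n_subj, 0, 0.02)
    y <- 0.8 + u[as.integer(factor(d$subject_id))] +
      slope * d$session_number + rnorm(nrow(d), 0, 0.02)
    d$prop_pos <- pmin(y, 1)^2
    d
  }
  fits <- lapply(1:100, function(r) {
    fit_choice_trend(make_choice_data(0.02, seed = 400 + r))
  })
  slopes <- vapply(fits, function(f) {
    f$coefficients$estimate[f$coefficients$term == "session_number"]
  }, numeric(1))
  expect_gte(mean(abs(slopes - 0.02) <= 0.01), 0.9)

  f <- fits[[1]]
  expect_gte(f$lrt$chisq, 0)
  # oracle: deviance change recomputed from the two log-likelihoods
  d <- make_choice_data(0.02, seed = 401)
  d$y <- sqrt(d$prop_pos)
  full <- nlme::lme(y ~ session_number, random = ~ 1 | subject_id, data = d,
                    method = "ML")
  null <- nlme::lme(y ~ 1, random = ~ 1 | subject_id, data = d,
                    method = "ML")
  expect_equal(fits[[1]]$lrt$chisq,
               as.numeric(2 * (logLik(full) - logLik(null))),
               tolerance = 1e-6)

  # degenerate: constant proportions
  cst <- make_choice_data(0, seed = 1)
  cst$prop_pos <- 0.75
  expect_warning(f0 <- fit_choice_trend(cst), "boundary")
  expect_equal(f0$coefficients$estimate[2], 0)
  expect_equal(f0$lrt$p, 1)
})
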