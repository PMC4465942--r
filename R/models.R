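#' Model-fit container
#'
#' All fitting functions return a list of class `jb_model_fit` with:
#' `formula` (character), `coefficients` (data frame `term`, `estimate`,
#' `se`), `anova` (data frame `term`, `df_num`, `df_den`, `F`, `p`;
#' sequential type-I sums of squares, terms in the order given to the
#' fit), `lrt` (for mixed fits: `chisq`, `df`, `p`), `n_obs`,
#' `response_scale` and the underlying `fit` object.
#'
#' @name jb_model_fit
#' @keywords internal
NULL

as_jb_fit <- function(fit, formula_str, anova_df, n_obs, response_scale,
                      lrt = NULL) {
  cf <- if (inherits(fit, "lme")) {
    tt <- summary(fit)$tTable
    data.frame(term = rownames(tt), estimate = tt[, "Value"],
               se = tt[, "Std.Error"], row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(formula = formula_str, coefficients = cf,
                 anova = anova_df, lrt = lrt, n_obs = n_obs,
                 response_scale = response_scale, fit = fit),
            class = "jb_model_fit")
}

#' @export
print.jb_model_fit <- function(x, ...) {
  cat("<jb_model_fit>", x$formula, "| n =", x$n_obs,
      "| response:", x$response_scale, "\n")
  if (!is.null(x$anova)) print(x$anova, digits = 4)
  if (!is.null(x$lrt)) {
    cat(sprintf("LRT: chisq(%d) = %.3f, p = %.4g\n",
                x$lrt$df, x$lrt$chisq, x$lrt$p))
  }
  invisible(x)
}

lm_anova_table <- function(fit) {
  a <- stats::anova(fit)
  terms <- rownames(a)
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df_num = a$Df[keep],
             df_den = a$Df[!keep], F = a$`F value`[keep],
             p = a$`Pr(>F)`[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Overall-speed model: POS/NEG test latencies by subject and session
#'
#' Fits a general linear model of reciprocal latency on the responded POS
#' and NEG test trials, with subject, session and their interaction as
#' categorical fixed predictors.  A significant subject-by-session
#' interaction indicates that overall speed varies between subjects and
#' days, motivating the per-session speed covariate in the
#' intermediate-cone analysis.
#'
#' @param test_trials Responded POS/NEG test trials (e.g. from
#'   [filter_test_trials()]); must span at least two subjects and two
#'   sessions.
#' @return A [`jb_model_fit`] whose ANOVA table carries the F-test of the
#'   `subject:session` interaction.
#' @export
fit_posneg_latency_model <- function(test_trials) {
  d <- test_trials[test_trials$valence %in% c("POS", "NEG") &
                     test_trials$responded, , drop = FALSE]
  d$chimp <- factor(d$subject_id)
  # test-session number within subject (subjects reach testing at
  # different absolute session ordinals)
  d$session <- factor(stats::ave(d$session_ordinal, d$subject_id,
                                 FUN = function(x) match(x, sort(unique(x)))))
  if (nlevels(d$chimp) < 2 || nlevels(d$session) < 2) {
    stop("estimability error: need >= 2 subjects and >= 2 sessions")
  }
  if (any(table(d$chimp, d$session) == 0)) {
    stop("estimability error: empty subject x session cells")
  }
  d$y <- reciprocal_transform(d$latency_s)
  fit <- stats::lm(y ~ chimp * session, data = d)
  as_jb_fit(fit, "1/latency ~ chimp * session", lm_anova_table(fit),
            nrow(d), "reciprocal_latency")
}

#' Intermediate-cone model with speed covariate
#'
#' Fits a general linear model of reciprocal latency on the responded
#' intermediate (NP/M/NN) test trials, with subject (categorical), valence
#' (continuous percent grey) and their interaction as predictors and the
#' per-session speed covariate (see [session_speed()]) controlling for
#' motivation.  Terms enter sequentially (type-I sums of squares) with the
#' covariate first -- `speed + chimp + valence + chimp:valence` -- so that
#' the subject and valence tests are adjusted for overall speed.
#'
#' @param intermediate_trials Responded NP/M/NN test trials.
#' @param speeds Data frame with columns `subject_id`, `session_id`,
#'   `speed` -- one row per test session (e.g. built with
#'   [session_speed()]).
#' @return A [`jb_model_fit`].  If the speed covariate has zero variance
#'   the fit drops it and flags `degenerate_speed = TRUE`.
#' @export
fit_intermediate_model <- function(intermediate_trials, speeds) {
  d <- intermediate_trials[
    intermediate_trials$valence %in% .intermediate_labels &
      intermediate_trials$responded, , drop = FALSE]
  key_d <- paste(d$subject_id, d$session_id)
  key_s <- paste(speeds$subject_id, speeds$session_id)
  idx <- match(key_d, key_s)
  if (anyNA(idx)) {
    stop("linkage error: no speed for session(s) ",
         paste(unique(key_d[is.na(idx)]), collapse = ", "))
  }
  d$speed <- speeds$speed[idx]
  d$chimp <- factor(d$subject_id)
  if (nlevels(d$chimp) < 2) stop("estimability error: need >= 2 subjects")
  d$valence_num <- grey_for_valence(d$valence)
  d$y <- reciprocal_transform(d$latency_s)
  degenerate <- stats::var(d$speed) == 0
  fit <- if (degenerate) {
    stats::lm(y ~ chimp + valence_num + chimp:valence_num, data = d)
  } else {
    stats::lm(y ~ speed + chimp + valence_num + chimp:valence_num, data = d)
  }
  out <- as_jb_fit(fit,
                   if (degenerate)
                     "1/latency ~ chimp + valence + chimp:valence [speed constant, dropped]"
                   else "1/latency ~ speed + chimp + valence + chimp:valence",
                   lm_anova_table(fit), nrow(d), "reciprocal_latency")
  out$degenerate_speed <- degenerate
  out$data <- d
  out
}

#' Tukey HSD contrasts between subjects
#'
#' All pairwise comparisons between levels of the subject factor of a
#' fitted latency model, on adjusted means: each subject's prediction is
#' evaluated at the grand mean of every other model term (mean valence,
#' mean speed), differences are tested with the studentized-range
#' distribution (family-wise 95% intervals and adjusted p-values).  Note
#' that models fit on the reciprocal scale reverse the ordering of mean
#' latencies: a *larger* adjusted mean is a *faster* subject.
#'
#' @param fit A [`jb_model_fit`] from [fit_intermediate_model()] or
#'   [fit_posneg_latency_model()], or any `lm` fit with a factor named
#'   `chimp` and stored `data`.
#' @param conf_level Family-wise confidence level.
#' @return A data frame of class `jb_tukey` with columns `pair`, `diff`,
#'   `ci_low`, `ci_high`, `p_adjusted` (differences on the model's
#'   response scale).
#' @export
tukey_hsd <- function(fit, conf_level = 0.95) {
  lmfit <- if (inherits(fit, "jb_model_fit")) fit$fit else fit
  d <- if (inherits(fit, "jb_model_fit") && !is.null(fit$data)) fit$data
       else stats::model.frame(lmfit)
  if (!"chimp" %in% names(d)) stop("no subject factor 'chimp' in fit")
  levs <- levels(d$chimp)
  if (length(levs) < 2) stop("need >= 2 subject levels")

  # adjusted mean for each subject: predict at the mean of all covariates
  ref <- d[1, , drop = FALSE]
  num <- names(d)[vapply(d, is.numeric, logical(1))]
  for (v in setdiff(num, "y")) ref[[v]] <- mean(d[[v]])
  grid <- ref[rep(1, length(levs)), , drop = FALSE]
  grid$chimp <- factor(levs, levels = levs)
  # average over any remaining factor (e.g. session): use first level's
  # prediction averaged over levels
  other_fac <- setdiff(names(d)[vapply(d, is.factor, logical(1))], "chimp")
  X <- 0
  if (length(other_fac)) {
    combos <- expand.grid(lapply(d[other_fac], levels),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      g <- grid
      for (f in other_fac) g[[f]] <- factor(combos[i, f],
                                            levels = levels(d[[f]]))
      X <- X + stats::model.matrix(stats::delete.response(stats::terms(lmfit)),
                                   g)
    }
    X <- X / nrow(combos)
  } else {
    X <- stats::model.matrix(stats::delete.response(stats::terms(lmfit)), grid)
  }

  beta <- stats::coef(lmfit)
  V <- stats::vcov(lmfit)
  df_res <- stats::df.residual(lmfit)
  m <- length(levs)
  pairs <- utils::combn(m, 2)
  qcrit <- stats::qtukey(conf_level, m, df_res)
  out <- apply(pairs, 2, function(pr) {
    cvec <- X[pr[2], ] - X[pr[1], ]
    diff <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    stat <- abs(diff) / se * sqrt(2)
    p <- stats::ptukey(stat, m, df_res, lower.tail = FALSE)
    half <- qcrit * se / sqrt(2)
    c(diff = diff, ci_low = diff - half, ci_high = diff + half,
      p_adjusted = p)
  })
  res <- data.frame(pair = paste(levs[pairs[2, ]], levs[pairs[1, ]],
                                 sep = "-"),
                    t(out), row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("jb_tukey", "data.frame")
  res
}

#' Choice-preference trend across sessions
#'
#' Fits a linear mixed model of the square-root-transformed per-session
#' proportion of POS-first choices on session number (continuous), with a
#' random intercept per subject, by maximum likelihood ([nlme::lme()]).
#' The session slope is tested by the change in deviance when it is
#' dropped (likelihood-ratio chi-squared with 1 df).  A positive slope
#' means the preference for the positive cone strengthens over choice
#' sessions.
#'
#' @param choice_summaries Data frame with columns `subject_id`,
#'   `session_number` and `prop_pos` (proportion of POS-first choices, in
#'   \[0, 1\]); at least two subjects with two sessions each.
#' @return A [`jb_model_fit`] with `lrt` filled in; the session slope is
#'   the `session_number` row of `coefficients`.
#' @export
fit_choice_trend <- function(choice_summaries) {
  d <- choice_summaries
  need <- c("subject_id", "session_number", "prop_pos")
  if (!all(need %in% names(d))) {
    stop("choice_summaries needs columns ", paste(need, collapse = ", "))
  }
  if (length(unique(d$subject_id)) < 2 ||
      length(unique(d$session_number)) < 2) {
    stop("estimability error: need >= 2 subjects and >= 2 sessions")
  }
  d$y <- sqrt_prop_transform(d$prop_pos)
  d$subject_id <- factor(d$subject_id)
  if (stats::var(d$y) == 0) {
    warning("boundary: all transformed proportions identical; slope is 0")
    return(structure(list(formula = "sqrt(prop_pos) ~ session_number, random ~1|subject",
                          coefficients = data.frame(
                            term = c("(Intercept)", "session_number"),
                            estimate = c(d$y[1], 0), se = c(NA_real_, 0),
                            stringsAsFactors = FALSE),
                          anova = NULL,
                          lrt = list(chisq = 0, df = 1L, p = 1),
                          n_obs = nrow(d),
                          response_scale = "sqrt_proportion", fit = NULL),
                     class = "jb_model_fit"))
  }
  full <- nlme::lme(y ~ session_number, random = ~ 1 | subject_id,
                    data = d, method = "ML")
  null <- nlme::lme(y ~ 1, random = ~ 1 | subject_id,
                    data = d, method = "ML")
  chisq <- max(0, 2 * (stats::logLik(full) - stats::logLik(null)))
  lrt <- list(chisq = as.numeric(chisq), df = 1L,
              p = stats::pchisq(as.numeric(chisq), 1, lower.tail = FALSE))
  as_jb_fit(full, "sqrt(prop_pos) ~ session_number, random ~1|subject",
            NULL, nrow(d), "sqrt_proportion", lrt = lrt)
}
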