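#' Reciprocal transform of a latency
#'
#' Latencies to touch the cone are right-skewed; analyses of latency models
#' run on the reciprocal scale (1/latency, i.e. a speed).  The 61-s code
#' given to training non-responses passes through the transform like any
#' other latency.
#'
#' @param latency_s Numeric vector of latencies in seconds; all must be
#'   strictly positive.
#' @return `1 / latency_s`.
#' @export
#' @examples
#' reciprocal_transform(c(2, 61))
reciprocal_transform <- function(latency_s) {
  if (!is.numeric(latency_s) || any(is.na(latency_s)) || any(latency_s <= 0)) {
    stop("latency_s must be strictly positive (got non-positive or NA values)")
  }
  1 / latency_s
}

#' Square-root transform of a proportion
#'
#' Used to stabilise the variance of per-session proportions of positive
#' choices before model fitting.
#'
#' @param p Numeric vector of proportions in \[0, 1\].
#' @return `sqrt(p)`.
#' @export
sqrt_prop_transform <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p must be a proportion in [0, 1]")
  }
  sqrt(p)
}

#' Two-sample t-test on latencies
#'
#' Thin wrapper around [stats::t.test()] returning the fields the
#' progression criteria and reports need.  The Welch (unequal-variance)
#' variant with Satterthwaite degrees of freedom is the default; the pooled
#' variant (`df = n_a + n_b - 2`) is available as an option.
#'
#' @param a,b Numeric samples (POS and NEG latencies, respectively), each
#'   with at least two values.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A list of class `jb_t_test` with elements `t`, `df`,
#'   `p_two_tailed`, `mean_a`, `mean_b`, `direction_predicted` (`TRUE` when
#'   `mean_a < mean_b`, i.e. POS faster than NEG) and `variant`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))
two_sample_t <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each sample needs at least 2 values")
  }
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2, p_two_tailed = 1,
                  mean_a = mean(a), mean_b = mean(b),
                  direction_predicted = FALSE, variant = variant)
      class(res) <- "jb_t_test"
      return(res)
    }
    stop("insufficient data: both samples are constant")
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  res <- list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_two_tailed = tt$p.value,
    mean_a = mean(a),
    mean_b = mean(b),
    direction_predicted = mean(a) < mean(b),
    variant = variant
  )
  class(res) <- "jb_t_test"
  res
}

#' Exact two-tailed binomial test against chance
#'
#' Computes the exact two-tailed p-value for `k` successes in `n` trials
#' under a null success probability of 1/2, by tail doubling:
#' `p = min(1, 2 * P(X >= max(k, n - k)))`.  At a symmetric null this
#' coincides with summing both tails.
#'
#' @param k Number of successes (e.g. trials where the positive cone was
#'   touched first).
#' @param n Number of trials.
#' @return A list of class `jb_binomial` with elements `k`, `n` and
#'   `p_two_tailed`.
#' @export
#' @examples
#' binomial_two_tailed(20, 24)$p_two_tailed
binomial_two_tailed <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("require integers 0 <= k <= n with n >= 1")
  }
  hi <- max(k, n - k)
  p <- min(1, 2 * stats::pbinom(hi - 1, n, 0.5, lower.tail = FALSE))
  res <- list(k = as.integer(k), n = as.integer(n), p_two_tailed = p)
  class(res) <- "jb_binomial"
  res
}

#' Smallest significant choice count
#'
#' Enumerates the exact two-tailed binomial p-value for every `k` from
#' `ceiling(n/2)` upward and returns the smallest `k` whose p-value is
#' strictly below `alpha` -- the minimum number of positive-first choices in
#' an `n`-trial choice session that counts as a significant preference.
#'
#' @param n Number of choice trials in the session.
#' @param alpha Significance level.
#' @return Integer threshold, or `NA` if no `k <= n` reaches significance.
#' @export
#' @examples
#' min_significant_choices(24, 0.05)  # 18
min_significant_choices <- function(n, alpha = 0.05) {
  if (n < 1 || alpha <= 0 || alpha >= 1) {
    stop("require n >= 1 and alpha in (0, 1)")
  }
  for (k in seq(ceiling(n / 2), n)) {
    if (binomial_two_tailed(k, n)$p_two_tailed < alpha) return(as.integer(k))
  }
  NA_integer_
}

#' Cohen's d with pooled standard deviation
#'
#' Effect size of the difference in means between two samples:
#' `d = (mean(a) - mean(b)) / s_p`, with
#' `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric samples with at least two values each.
#' @return A list of class `jb_effect_size` with elements `d` and
#'   `pooled_sd`.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))$d  # -2
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("degenerate input: pooled standard deviation is zero")
  res <- list(d = (mean(a) - mean(b)) / sp, pooled_sd = sp)
  class(res) <- "jb_effect_size"
  res
}
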