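# Evaluation statistics for the user studies: one-sample Wilcoxon signed-rank
# tests against the neutral scale value (exact via the signed-rank null
# distribution, which equals full 2^n sign enumeration), one-sample t tests
# from summary statistics, Likert mean/SD summaries, and the Net Promoter
# Score with its published category bins.

#' Likert sample
#'
#' @param values integer responses on the stated scale.
#' @param scale_min,scale_max scale bounds (default 1-7).
#' @param neutral the test value for one-sample location tests (default 4).
#' @return A `likert_sample`.
#' @export
likert_sample <- function(values, scale_min = 1, scale_max = 7, neutral = 4) {
  assert_that(length(values) >= 1 && all(values >= scale_min & values <= scale_max),
              sprintf("all values must lie in [%g, %g]", scale_min, scale_max))
  structure(list(values = as.numeric(values), scale_min = scale_min,
                 scale_max = scale_max, neutral = neutral),
            class = "likert_sample")
}

# exact null distribution of the signed-rank statistic W = sum of ranks of
# positive differences under random signs. Convolution over the doubled
# (mid)ranks; counts are exact in double precision for n <= 25 (2^25 < 2^53).
# Equivalent to enumerating all 2^n sign assignments.
signed_rank_null_counts <- function(ranks2) {
  counts <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts)
    counts <- c(counts, rep(0, r)) + shifted
  }
  counts  # counts[w + 1] = #assignments with 2*W = w
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests a sample's location against the neutral scale value. Differences of
#' zero are discarded (the standard convention), midranks handle ties, the
#' exact null distribution is used when the effective sample size is at most
#' 25 and a normal approximation with tie correction and continuity
#' correction otherwise. The two-sided p value doubles the smaller exact tail
#' and is capped at 1.
#'
#' @param sample a [likert_sample()] (its `neutral` is the test value).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param exact_max largest effective n for which the exact distribution is
#'   used.
#' @return A `test_result` with `statistic` (V, the positive-rank sum),
#'   `p_value`, `n_effective` and `method` ("exact" or
#'   "normal-approximation").
#' @export
wilcoxon_one_sample <- function(sample, alternative = c("two.sided", "greater", "less"),
                                exact_max = 25) {
  alternative <- match.arg(alternative)
  d <- sample$values - sample$neutral
  d <- d[d != 0]
  if (length(d) == 0) {
    stop_squatcoach("degenerate_sample", "all differences from the test value are zero")
  }
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])

  if (n <= exact_max) {
    counts <- signed_rank_null_counts(as.integer(round(2 * r)))
    total <- 2^n
    w2 <- round(2 * W)
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p_le <- sum(counts[1:(w2 + 1)]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z_ge <- (W - mu - cc) / sqrt(sigma2)
    z_le <- (W - mu + cc) / sqrt(sigma2)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    method <- "normal-approximation"
  }
  test_result(statistic = W, p_value = p, n_effective = n, method = method)
}

#' Test-result container
#'
#' @param statistic test statistic.
#' @param p_value p value in [0, 1].
#' @param n_effective effective sample size used by the test.
#' @param method "exact", "normal-approximation" or "t".
#' @return A `test_result`.
#' @export
test_result <- function(statistic, p_value, n_effective, method) {
  assert_that(p_value >= 0 && p_value <= 1, "p_value must be in [0, 1]")
  structure(list(statistic = statistic, p_value = p_value,
                 n_effective = n_effective, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n_effective))
  invisible(x)
}

#' One-sample t test from summary statistics
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (n - 1 denominator), positive.
#' @param n sample size, at least 2.
#' @param mu test value (default 4, the neutral scale value).
#' @return A `test_result` with the t statistic, two-sided p value from the t
#'   distribution with `n - 1` degrees of freedom, and method "t".
#' @export
t_one_sample <- function(mean, sd, n, mu = 4) {
  assert_that(n >= 2, "n must be at least 2")
  if (sd <= 0) stop_squatcoach("degenerate_sample", "sd must be positive")
  t_stat <- (mean - mu) / (sd / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  test_result(statistic = t_stat, p_value = p, n_effective = as.integer(n), method = "t")
}

#' Net Promoter Score sample
#'
#' @param ratings integer recommendation ratings.
#' @param scale_min,scale_max rating bounds (default the standard 0-10 item).
#' @param promoter_min lowest rating counted as promoter (default 9).
#' @param detractor_max highest rating counted as detractor (default 6).
#' @return An `nps_sample`.
#' @export
nps_sample <- function(ratings, scale_min = 0, scale_max = 10,
                       promoter_min = 9, detractor_max = 6) {
  assert_that(length(ratings) >= 1 && all(ratings >= scale_min & ratings <= scale_max),
              sprintf("ratings must lie in [%g, %g]", scale_min, scale_max))
  assert_that(detractor_max < promoter_min, "detractor_max must be below promoter_min")
  structure(list(ratings = as.numeric(ratings), scale_min = scale_min,
                 scale_max = scale_max, promoter_min = promoter_min,
                 detractor_max = detractor_max),
            class = "nps_sample")
}

#' Net Promoter Score
#'
#' `score = 100 * (#promoters - #detractors) / n`, i.e. the percentage of
#' detractors subtracted from the percentage of promoters. Scores are binned
#' into the published categories: -100 to 0 needs improvement, 1 to 30 good,
#' 31 to 70 great, 71 to 100 excellent.
#'
#' @param sample an [nps_sample()].
#' @return List with `score`, `category`, `promoters`, `detractors`,
#'   `passives`, `n`.
#' @export
net_promoter_score <- function(sample) {
  r <- sample$ratings
  promoters <- sum(r >= sample$promoter_min)
  detractors <- sum(r <= sample$detractor_max)
  n <- length(r)
  score <- 100 * (promoters - detractors) / n
  category <- if (score <= 0) "needs improvement"
  else if (score <= 30) "good"
  else if (score <= 70) "great"
  else "excellent"
  list(score = score, category = category, promoters = promoters,
       detractors = detractors, passives = n - promoters - detractors, n = n)
}

#' Likert summary: mean and sample SD
#'
#' @param sample a [likert_sample()].
#' @return List with `mean`, `sd` (n - 1 denominator) and `n`, matching the
#'   "mean (SD)" reporting convention.
#' @export
likert_summary <- function(sample) {
  v <- sample$values
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v))
}
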