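stat_result <- function(method, statistic, p_value, n, aux = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n = n, aux = aux), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped (Wilcoxon's original treatment) and ties in
#' absolute value receive midranks. For n <= 20 with no ties the two-sided
#' p-value is exact, from the full distribution of the positive-rank sum over
#' all 2^n sign assignments (dynamic-programming enumeration); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The `exact` flag in `aux` records which path was taken.
#'
#' @param x numeric vector of paired differences.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; `NULL`
#'   chooses automatically. Exact is only available without ties.
#' @return A `stat_result`; statistic is W+ (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, exact = NULL) {
  n_zero <- sum(x == 0)
  d <- x[x != 0]
  n <- length(d)
  if (n == 0) stopf("all differences are zero: no information")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- if (is.null(exact)) (n <= 20 && !ties) else (exact && !ties)
  if (use_exact) {
    # distribution of W+ over all 2^n sign assignments; ranks are 1..n here
    M <- n * (n + 1) / 2
    f <- c(1, numeric(M))  # f[w + 1] = number of assignments with W+ = w
    for (ri in seq_len(n)) {
      g <- f
      g[(ri + 1):(M + 1)] <- g[(ri + 1):(M + 1)] + f[1:(M + 1 - ri)]
      f <- g
    }
    total <- 2^n
    p_ge <- sum(f[(W + 1):(M + 1)]) / total
    p_le <- sum(f[1:(W + 1)]) / total
    p <- min(1, 2 * min(p_ge, p_le))
    return(stat_result("Wilcoxon signed-rank (exact)", W, p, n,
                       aux = list(n_zero = n_zero, ties = ties, exact = TRUE)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z_num <- W - mu
  cc <- if (z_num == 0) 0 else sign(z_num) * 0.5
  z <- (z_num - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  stat_result("Wilcoxon signed-rank (normal approximation)", W, p, n,
              aux = list(n_zero = n_zero, ties = ties, exact = FALSE, z = z))
}

#' One-sample t-test against a reference mean
#'
#' `t = (mean - mu0) / (s / sqrt(n))`, df = n - 1, two-sided p from the t
#' distribution. Returns mean and standard error of the mean (SEM) in `aux`
#' for mean-plus-minus-SEM reporting.
#'
#' @param x numeric scores, n >= 2, non-degenerate.
#' @param mu0 reference mean (default 0 = "equal quality").
#' @return A `stat_result`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  n <- length(x)
  if (n < 2) stopf("need n >= 2")
  s <- stats::sd(x)
  if (s == 0) stopf("zero variance: t undefined")
  sem <- s / sqrt(n)
  t_stat <- (mean(x) - mu0) / sem
  df <- n - 1
  p <- 2 * stats::pt(-abs(t_stat), df)
  stat_result("one-sample t", t_stat, p, n,
              aux = list(mean = mean(x), sem = sem, df = df))
}

# Lilliefors-type KS distance of x against a normal with x's own moments
ks_distance <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  cdf <- stats::pnorm(z)
  max(seq_len(n) / n - cdf, cdf - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' KS distance between the sample and a normal distribution with the
#' sample's own mean and SD. Because the parameters are estimated, the null
#' distribution of the distance is calibrated by Monte Carlo
#' (Lilliefors-style): `reps` seeded standard-normal samples of the same
#' size.
#'
#' @param x numeric sample, n >= 5, non-degenerate.
#' @param reps Monte-Carlo replicates (>= 1000 recommended; default 10000).
#' @param seed RNG seed for the null calibration.
#' @return A `stat_result`; statistic is the KS distance D.
#' @export
ks_normality <- function(x, reps = 10000, seed = 1L) {
  n <- length(x)
  if (n < 5) stopf("need n >= 5")
  if (stats::sd(x) == 0) stopf("zero variance")
  D <- ks_distance(x)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(reps))
      if (ks_distance(stats::rnorm(n)) >= D) cnt <- cnt + 1L
    cnt
  })
  p <- (1 + exceed) / (reps + 1)
  stat_result("Kolmogorov-Smirnov normality (Monte-Carlo null)", D, p, n,
              aux = list(reps = reps, seed = seed))
}

#' Kendall's coefficient of concordance W
#'
#' Agreement among m raters ranking k items. Items are midranked within each
#' rater; with `S` the sum of squared deviations of the item rank sums and
#' `T_i` the tie correction of rater i,
#' `W = 12 S / (m^2 (k^3 - k) - m * sum(T_i))`. The large-sample p-value uses
#' `chi^2 = m (k - 1) W` with k - 1 df (needs k >= 3; otherwise W is returned
#' with a flag and no p). The agreement band follows the conventional
#' thresholds 0 (none), 0.1 (weak), 0.3 (moderate), 0.6 (strong), 1
#' (perfect).
#'
#' @param ratings m x k numeric matrix (raters in rows, items in columns),
#'   e.g. a [rating_matrix()].
#' @return A `stat_result`; statistic is W, `aux$band` the agreement band.
#' @export
kendalls_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  m <- nrow(ratings); k <- ncol(ratings)
  if (m < 2 || k < 2) stopf("need >= 2 raters and >= 2 items")
  rk <- t(apply(ratings, 1, rank))
  R <- colSums(rk)
  S <- sum((R - mean(R))^2)
  Ti <- apply(rk, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  })
  denom <- m^2 * (k^3 - k) - m * sum(Ti)
  if (denom == 0) stopf("all raters gave constant scores: W undefined")
  W <- 12 * S / denom
  band <- if (W >= 1) "perfect" else if (W >= 0.6) "strong"
  else if (W >= 0.3) "moderate" else if (W >= 0.1) "weak" else "none"
  if (k >= 3) {
    chi2 <- m * (k - 1) * W
    p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
    aux <- list(band = band, chi2 = chi2, df = k - 1, m = m, k = k)
  } else {
    p <- NA_real_
    aux <- list(band = band, m = m, k = k,
                note = "p-value needs k >= 3 items")
  }
  stat_result("Kendall's W", W, p, k, aux = aux)
}

#' Convert a correlation-type effect size r to Cohen's d
#'
#' `d = 2 r / sqrt(1 - r^2)`.
#'
#' @param r correlation effect size, |r| < 1.
#' @return Cohen's d.
#' @export
effect_r_to_d <- function(r) {
  if (abs(r) >= 1) stopf("|r| must be < 1")
  2 * r / sqrt(1 - r^2)
}

#' Simulation-based power of a paired two-sided test
#'
#' Draws `reps` samples of `n` differences from `Normal(effect_d, 1)`, runs
#' the chosen two-sided test at level `alpha`, and returns the rejection
#' fraction with its binomial Monte-Carlo standard error.
#'
#' @param test `"wilcoxon"` (signed-rank) or `"t"` (one-sample t).
#' @param n sample size (>= 5).
#' @param effect_d standardized mean difference (Cohen's d); see
#'   [effect_r_to_d()] for correlation-type effects.
#' @param alpha two-sided significance level, in (0, 1).
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed RNG seed.
#' @return List with `power`, `se` (Monte-Carlo SE), `reps`, `n`,
#'   `effect_d`, `alpha`.
#' @export
simulate_power <- function(test = c("wilcoxon", "t"), n, effect_d,
                           alpha = 0.05, reps = 1000, seed = 1L) {
  test <- match.arg(test)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (n < 5) stopf("need n >= 5")
  if (reps < 1000) stopf("need reps >= 1000")
  run <- switch(test,
    wilcoxon = function(x) wilcoxon_signed_rank(x)$p_value,
    t = function(x) one_sample_t(x)$p_value)
  rejections <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(reps))
      if (run(stats::rnorm(n, effect_d)) < alpha) cnt <- cnt + 1L
    cnt
  })
  power <- rejections / reps
  list(power = power, se = sqrt(power * (1 - power) / reps),
       reps = reps, n = n, effect_d = effect_d, alpha = alpha)
}

#' Signed Likert rating matrix
#'
#' Raters x items integer scores in [-3, 3]: magnitude per the 0-3 "how much
#' better" scale, sign encoding which modality wins (negative = DSA better,
#' positive = DVA better).
#'
#' @param scores m x k matrix of integers in [-3, 3], m >= 2, k >= 2.
#' @return The validated matrix with class `rating_matrix`.
#' @export
rating_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2 || ncol(scores) < 2)
    stopf("need >= 2 raters and >= 2 items")
  if (any(scores != round(scores)) || any(abs(scores) > 3))
    stopf("scores must be integers in [-3, 3]")
  structure(scores, class = c("rating_matrix", class(scores)))
}

#' Simulate Likert ratings of paired image quality
#'
#' Synthetic raters for exercising the concordance and t-test machinery (no
#' claim of modeling human readers): each rating is
#' `clamp(round(gain_i * delta_q + eps), -3, 3)` with rater-specific noise
#' `eps ~ Normal(0, noise_sd)`.
#'
#' @param delta_q per-item true quality difference (positive = DVA better).
#' @param m number of raters (>= 2).
#' @param gain scalar or per-rater response gain.
#' @param noise_sd rater noise SD.
#' @param seed RNG seed.
#' @return A [rating_matrix()] (m x length(delta_q)).
#' @export
likert_rater_sim <- function(delta_q, m = 5, gain = 1, noise_sd = 1,
                             seed = 1L) {
  if (m < 2) stopf("need m >= 2 raters")
  k <- length(delta_q)
  gain <- rep_len(gain, m)
  scores <- with_seed(seed, {
    t(vapply(seq_len(m), function(i) {
      raw <- gain[i] * delta_q + stats::rnorm(k, 0, noise_sd)
      pmin(pmax(round(raw), -3), 3)
    }, numeric(k)))
  })
  rating_matrix(scores)
}
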