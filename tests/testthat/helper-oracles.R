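# Independent oracles used across tests; each deliberately takes the dumbest
# possible route (explicit loops, full enumeration) so it shares no code path
# with the implementation it checks.

# per-pixel two-pass SD of log intensity over time
naive_dva <- function(frames) {
  d <- dim(frames)
  out <- matrix(0, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    v <- log(frames[y, x, ])
    m <- sum(v) / length(v)
    out[y, x] <- sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  out
}

# two-sided signed-rank p by enumerating all 2^n sign assignments
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(ws >= W), mean(ws <= W)))
}

# linear-interpolation percentile from first principles (sorted order stat)
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# smooth positive random image for registration tests
smooth_test_image <- function(n = 128, seed = 1, scale = 6) {
  set.seed(seed)
  base <- matrix(stats::rnorm(n * n), n)
  k <- outer(stats::dnorm(c(0:(n %/% 2), -((n - n %/% 2 - 1):1)), sd = scale),
             stats::dnorm(c(0:(n %/% 2), -((n - n %/% 2 - 1):1)), sd = scale))
  sm <- Re(stats::fft(stats::fft(base) * stats::fft(k), inverse = TRUE)) / n^2
  sm / stats::sd(sm)
}

# small, fast phantom configuration for unit tests
tiny_config <- function(..., n_frames = 10, seed = 42L) {
  phantom_config(height_px = 128, width_px = 128, n_frames = n_frames,
                 seed = seed, ...)
}
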