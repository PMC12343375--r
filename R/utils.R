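#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so library internals never perturb a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a child RNG seed from a master seed and a stage label
#'
#' Deterministic arithmetic hash (multiply-add modulo 2^31 - 1) of the master
#' seed and any number of integer or character parts. The same
#' (master, parts...) always yields the same child seed, so any stage of a
#' larger experiment can be re-run in isolation.
#'
#' @param master integer master seed.
#' @param ... integer or character stage identifiers.
#' @return A positive integer seed below 2^31 - 1.
#' @export
#' @examples
#' derive_seed(1, "noise", 3L)
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  acc <- as.numeric(master) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(part) else as.numeric(part)
    for (v in codes) acc <- (acc * 48271 + (v %% m) + 1) %% m
  }
  as.integer(acc %% (m - 2) + 1)
}

#' Expectation factor of the sample standard deviation
#'
#' For n iid Gaussian observations, `E[s] = c4(n) * sigma`. Used to predict
#' the mean background level of a variance image.
#'
#' @param n sample size (>= 2).
#' @return The c4 bias constant.
#' @export
c4_constant <- function(n) {
  stopifnot(n >= 2)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# DFT sample frequencies (cycles per sample), numpy fftfreq convention.
fftfreq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# quantile type 7 (linear interpolation), the convention used for all IQRs
quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
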