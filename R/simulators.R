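#' White Gaussian noise
#'
#' Independent standard-normal samples, reproducible from `seed` without
#' disturbing the caller's random-number state.
#'
#' @param n Number of samples, >= 1.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
white_noise <- function(n, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  .with_seed(seed, rnorm(n))
}

#' Pink (1/f) noise by spectral shaping
#'
#' Gaussian white noise is taken to the frequency domain, each bin's
#' amplitude is scaled by `1/sqrt(f)` (the DC bin is zeroed), and the
#' result transformed back and standardized to zero mean and unit
#' variance.  The target power spectral density is therefore exactly
#' proportional to `1/f`.
#'
#' @param n Number of samples, >= 2.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with mean 0 and unit variance.
#' @export
pink_noise <- function(n, seed = NULL) {
  if (n < 2) stop("`n` must be >= 2")
  wht <- .with_seed(seed, rnorm(n))
  spec <- fft(wht)
  freq <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))
  amp <- ifelse(freq == 0, 0, 1 / sqrt(freq))
  x <- Re(fft(spec * amp, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Default autoregressive coefficients
#'
#' The geometric scheme `alpha_i = 1 / 2^i`, i = 1..p: each additional
#' order adds a weaker echo of a more distant past sample, so higher
#' orders mean stronger temporal correlation.
#'
#' @param p AR order, 0..8 (0 gives an empty vector: pure white noise).
#' @return Numeric vector of length `p`.
#' @export
ar_coefficients <- function(p) {
  p <- as.integer(p)
  if (p < 0 || p > 8) stop("AR order `p` must be in 0..8")
  if (p == 0L) return(numeric(0))
  1 / 2^seq_len(p)
}

#' Autoregressive process
#'
#' `x_t = sum_i alpha_i x_{t-i} + n_t` with unit-variance zero-mean
#' Gaussian innovations, zero initial history, and a discarded burn-in
#' so the retained samples are effectively stationary.  Order 0 is plain
#' white Gaussian noise.
#'
#' @param n Number of retained samples.
#' @param order AR order `p`, 0..8.
#' @param coefficients AR coefficients; defaults to [ar_coefficients()].
#' @param seed Optional integer seed.
#' @param burn_in Number of leading samples discarded (default 1000).
#' @return Numeric vector of length `n`.
#' @export
ar_process <- function(n, order, coefficients = ar_coefficients(order),
                       seed = NULL, burn_in = 1000L) {
  order <- as.integer(order)
  if (length(coefficients) != order)
    stop(sprintf("expected %d coefficients, got %d", order, length(coefficients)))
  if (n < 1) stop("`n` must be >= 1")
  innov <- .with_seed(seed, rnorm(n + burn_in))
  x <- if (order == 0L) innov else
    as.numeric(stats::filter(innov, coefficients, method = "recursive",
                             init = rep(0, order)))
  x[(burn_in + 1L):(burn_in + n)]
}

#' Lorenz system trajectory
#'
#' Integrates the classic chaotic system
#' `dx/dt = 10 (y - x)`, `dy/dt = x (28 - z) - y`,
#' `dz/dt = x y - (8/3) z`
#' with a fixed-step fourth-order Runge-Kutta scheme and returns one
#' observed coordinate after a burn-in, one sample per integration step.
#'
#' @param n Number of recorded samples (default 50000).
#' @param dt Integration time step (default 0.001).
#' @param init Initial state `(x, y, z)` (default `c(1, 1, 1)`).
#' @param burn_in Number of leading steps discarded (default 5000).
#' @param coordinate Which coordinate to record: "x", "y" or "z".
#' @return Numeric vector of length `n`; deterministic given the spec.
#' @export
lorenz <- function(n = 50000L, dt = 0.001, init = c(1, 1, 1),
                   burn_in = 5000L, coordinate = c("x", "y", "z")) {
  coordinate <- match.arg(coordinate)
  if (n < 1) stop("`n` must be >= 1")
  if (dt <= 0) stop("`dt` must be > 0")
  f <- function(s) c(10 * (s[2L] - s[1L]),
                     s[1L] * (28 - s[3L]) - s[2L],
                     s[1L] * s[2L] - (8 / 3) * s[3L])
  ci <- match(coordinate, c("x", "y", "z"))
  total <- burn_in + n
  out <- numeric(total)
  s <- as.numeric(init)
  h <- dt
  for (i in seq_len(total)) {
    k1 <- f(s)
    k2 <- f(s + h / 2 * k1)
    k3 <- f(s + h / 2 * k2)
    k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i] <- s[ci]
  }
  out <- out[(burn_in + 1L):total]
  if (!all(is.finite(out)))
    stop("integration blew up: non-finite state encountered")
  out
}

#' Add white Gaussian noise at a prescribed signal-to-noise ratio
#'
#' The noise is scaled so that `10 log10(P_signal / P_noise)` equals
#' `snr_db` exactly, with power measured as the mean square.
#'
#' @param x Numeric signal with positive power.
#' @param snr_db Target signal-to-noise ratio in decibels; -10 dB means
#'   the noise carries ten times the signal power.
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric vector `x + noise`.
#' @export
add_noise_snr <- function(x, snr_db, seed = NULL) {
  p_sig <- mean(x^2)
  if (!is.finite(p_sig) || p_sig <= 0) stop("signal has zero power")
  noise <- .with_seed(seed, rnorm(length(x)))
  target <- p_sig / 10^(snr_db / 10)
  x + noise * sqrt(target / mean(noise^2))
}

# run code under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}
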