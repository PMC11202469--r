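#' Gaussian-CDF normalization of a time series
#'
#' Maps each sample through the cumulative distribution function of a
#' normal with the series' own mean and (population) variance, so the
#' output lies strictly in (0, 1).  The map is invariant under positive
#' affine rescaling of the input, which makes every downstream symbolic
#' statistic unit-free.
#'
#' @param x Numeric vector, the raw series.  Must be finite, of length
#'   at least 2, and non-constant.
#' @return Numeric vector in (0, 1) of the same length as `x`, with
#'   attributes `mu` (sample mean) and `sigma2` (population variance).
#' @examples
#' y <- ncdf_normalize(c(0, 2))      # pnorm(c(-1, 1))
#' @export
ncdf_normalize <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("`x` must be a numeric vector of length >= 2")
  if (!all(is.finite(x)))
    stop("`x` contains non-finite values")
  mu <- mean(x)
  sigma2 <- mean((x - mu)^2)
  if (sigma2 <= 0)
    stop("degenerate input: constant series (zero variance) cannot be normalized")
  y <- pnorm((x - mu) / sqrt(sigma2))
  attr(y, "mu") <- mu
  attr(y, "sigma2") <- sigma2
  y
}

#' Delay embedding
#'
#' Builds the trajectory matrix whose row `j` is
#' `(y[j], y[j + tau], ..., y[j + (m - 1) tau])`.
#'
#' @param y Numeric vector (typically a normalized series).
#' @param m Embedding dimension, integer >= 2.
#' @param tau Time delay, integer >= 1.
#' @return Numeric matrix with `length(y) - (m - 1) * tau` rows and `m`
#'   columns.
#' @export
delay_embed <- function(y, m, tau = 1L) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L) stop("embedding dimension `m` must be >= 2")
  if (tau < 1L) stop("time delay `tau` must be >= 1")
  n_rows <- length(y) - (m - 1L) * tau
  if (n_rows < 1L)
    stop(sprintf("series too short: need at least (m-1)*tau + 1 = %d samples, got %d",
                 (m - 1L) * tau + 1L, length(y)))
  Y <- matrix(0, n_rows, m)
  for (k in seq_len(m)) Y[, k] <- y[seq_len(n_rows) + (k - 1L) * tau]
  Y
}

#' Uniform quantization operator
#'
#' Assigns each value in `[y_min, y_max]` to one of `L` equal-width bins,
#' indexed 0 to L-1.  Bins are half-open on the right except the last,
#' which is closed at `y_max`.
#'
#' @param u Numeric vector of values to quantize.
#' @param y_min,y_max Range over which the bins are laid out
#'   (`y_max > y_min`); values outside the range are an error.
#' @param L Number of levels, integer >= 2.
#' @return Integer vector of bin indices in `0:(L - 1)`.
#' @export
uqo <- function(u, y_min, y_max, L) {
  L <- as.integer(L)
  if (L < 2L) stop("discretization level `L` must be >= 2")
  if (!(y_max > y_min)) stop("`y_max` must exceed `y_min`")
  if (any(u < y_min | u > y_max))
    stop("value outside the quantization range [y_min, y_max]")
  delta <- (y_max - y_min) / L
  pmin(as.integer(floor((u - y_min) / delta)), L - 1L)
}

#' Symbolize an embedded trajectory matrix
#'
#' The first column is quantized with [uqo()]; every later column `k`
#' stores the first column's bin plus the integer number of bin widths
#' separating `Y[, k]` from `Y[, 1]`, floored.  Raw symbols can fall
#' outside `0:(L-1)` (a large negative excursion, say), and are clipped
#' back into range so the alphabet stays at exactly `L^m` patterns.
#'
#' The bin range must be the min/max of the whole normalized series, not
#' of the matrix, so that every scale and window shares one bin layout
#' per series.
#'
#' @param Y Embedded matrix from [delay_embed()].
#' @param y_min,y_max Range of the normalized series `Y` was built from.
#' @param L Number of quantization levels.
#' @return An object of class `symbolic_phase_space`: a list with the
#'   integer symbol matrix `S`, the bin width `delta`, `y_min`, `y_max`,
#'   `L` and `m`.
#' @export
symbolize_phase_space <- function(Y, y_min, y_max, L) {
  if (!is.matrix(Y) || nrow(Y) < 1L) stop("`Y` must be a nonempty matrix")
  L <- as.integer(L)
  delta <- (y_max - y_min) / L
  s1 <- uqo(Y[, 1L], y_min, y_max, L)
  S <- s1 + floor((Y - Y[, 1L]) / delta)
  S <- pmin(pmax(S, 0), L - 1L)
  storage.mode(S) <- "integer"
  structure(
    list(S = S, delta = delta, y_min = y_min, y_max = y_max,
         L = L, m = ncol(Y)),
    class = "symbolic_phase_space")
}

#' Tally symbolic patterns into a probability distribution
#'
#' Each row of the symbol matrix is encoded as a mixed-radix integer with
#' base `L` (first element most significant:
#' `index = sum_k S[j, k] * L^(m - k)`), and relative frequencies are
#' taken over the `L^m` possible patterns.  Only observed patterns are
#' stored; the remaining probabilities are zero.
#'
#' @param S A `symbolic_phase_space`, or an integer matrix of symbols in
#'   `0:(L - 1)` together with `L`.
#' @param L Number of levels; taken from `S` when it is a
#'   `symbolic_phase_space`.
#' @return An object of class `pattern_distribution`: a list with
#'   `counts` (named by 0-based pattern index), `n_obs`, `n_states =
#'   L^m`, `L` and `m`.
#' @export
pattern_distribution <- function(S, L = NULL) {
  if (inherits(S, "symbolic_phase_space")) {
    L <- S$L
    S <- S$S
  }
  if (is.null(L)) stop("`L` must be supplied when `S` is a bare matrix")
  if (!is.matrix(S) || nrow(S) < 1L) stop("`S` must be a nonempty matrix")
  m <- ncol(S)
  n_states <- as.numeric(L)^m
  if (n_states > 2^53) stop("alphabet L^m too large to index")
  idx <- as.vector(S %*% as.numeric(L)^((m - 1L):0L))
  counts <- table(idx)
  structure(
    list(counts = stats::setNames(as.numeric(counts), names(counts)),
         n_obs = nrow(S), n_states = n_states, L = L, m = m),
    class = "pattern_distribution")
}

#' Pattern distribution of a raw series
#'
#' Convenience composition of [ncdf_normalize()], [delay_embed()],
#' [symbolize_phase_space()] and [pattern_distribution()].
#'
#' @inheritParams delay_embed
#' @param x Numeric vector, the raw series.
#' @param L Number of quantization levels.
#' @return A `pattern_distribution`.
#' @export
ipe_distribution <- function(x, m = 4L, tau = 1L, L = 4L) {
  y <- ncdf_normalize(x)
  Y <- delay_embed(y, m, tau)
  S <- symbolize_phase_space(Y, min(y), max(y), L)
  pattern_distribution(S)
}

#' Dense probability vector of a distribution
#'
#' @param d A `pattern_distribution` or a numeric probability vector.
#' @return Numeric vector of length `n_states` summing to 1.
#' @export
as_probabilities <- function(d) {
  if (is.numeric(d)) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8)
      stop("probabilities must be nonnegative and sum to 1")
    return(d / sum(d))
  }
  if (!inherits(d, "pattern_distribution"))
    stop("`d` must be a pattern_distribution or a probability vector")
  if (d$n_states > 1e7)
    stop("alphabet too large to expand densely; work with the sparse counts")
  P <- numeric(d$n_states)
  P[as.numeric(names(d$counts)) + 1] <- d$counts / d$n_obs
  P
}

#' Uniform and one-point reference distributions
#'
#' `uniform_distribution()` puts probability `1/n` on each of `n` states;
#' `delta_distribution()` concentrates all mass on a single state.  Both
#' are used as the reference points of the disequilibrium.
#'
#' @param n_states Number of states, integer >= 2.
#' @param state 1-based index of the loaded state (delta only).
#' @return A `pattern_distribution`.
#' @export
uniform_distribution <- function(n_states) {
  if (n_states < 2) stop("`n_states` must be >= 2")
  structure(
    list(counts = stats::setNames(rep(1, n_states), seq_len(n_states) - 1),
         n_obs = n_states, n_states = n_states, L = NA, m = NA),
    class = "pattern_distribution")
}

#' @rdname uniform_distribution
#' @export
delta_distribution <- function(n_states, state = 1L) {
  if (n_states < 2) stop("`n_states` must be >= 2")
  if (state < 1 || state > n_states) stop("`state` out of range")
  structure(
    list(counts = stats::setNames(1, state - 1),
         n_obs = 1, n_states = n_states, L = NA, m = NA),
    class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("<pattern_distribution> %d/%g states observed, %d patterns tallied\n",
              length(x$counts), x$n_states, x$n_obs))
  invisible(x)
}

#' @export
print.symbolic_phase_space <- function(x, ...) {
  cat(sprintf("<symbolic_phase_space> %d patterns of length %d, L = %d, delta = %.6g\n",
              nrow(x$S), x$m, x$L, x$delta))
  invisible(x)
}

# Compact representation used by the q-statistics: unique nonzero
# probabilities `p`, their multiplicities `w`, and the state count `n`.
# Grouping identical probabilities keeps the per-q cost proportional to
# the number of distinct pattern counts, not to L^m.
.dist_parts <- function(d) {
  if (inherits(d, "pattern_distribution")) {
    grp <- table(d$counts)
    p <- as.numeric(names(grp)) / d$n_obs
    w <- as.numeric(grp)
    return(list(p = p, w = w, n = d$n_states))
  }
  P <- as_probabilities(d)
  nz <- P[P > 0]
  list(p = nz, w = rep(1, length(nz)), n = length(P))
}
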