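#' The q-deformed logarithm
#'
#' `ln_q(x) = (x^(1-q) - 1) / (1 - q)` for `q != 1`, with the natural
#' logarithm as the `q -> 1` limit.  Values of `q` within `1e-9` of 1 are
#' routed through the logarithmic branch for numerical continuity.
#'
#' @param x Positive numeric vector.
#' @param q Nonnegative weighting parameter (scalar).
#' @return Numeric vector, the q-logarithm of `x`.
#' @examples
#' q_log(exp(1), 1)   # 1
#' q_log(3, 0)        # x - 1 = 2
#' @export
q_log <- function(x, q) {
  if (any(x <= 0)) stop("`x` must be strictly positive")
  if (q < 0) stop("`q` must be nonnegative")
  if (abs(q - 1) < 1e-9) return(log(x))
  (exp((1 - q) * log(x)) - 1) / (1 - q)
}

# sum_j w_j exp(q * a_j + (1 - q) * b_j), vectorized over q, evaluated in
# blocks so the intermediate matrix stays modest for long q grids.
# Combining both exponents in a single exp() avoids the overflow of
# b^(1-q) alone at large q.
.qab_sum <- function(a, b, w, qv) {
  out <- numeric(length(qv))
  d <- a - b
  blk <- max(1L, as.integer(2e7 / max(1L, length(a))))
  for (i0 in seq(1L, length(qv), by = blk)) {
    i <- i0:min(i0 + blk - 1L, length(qv))
    M <- exp(sweep(outer(qv[i], d), 2L, b, "+"))
    out[i] <- as.vector(M %*% w)
  }
  out
}

.is_one <- function(q) abs(q - 1) < 1e-9

#' Tsallis entropy of a pattern distribution
#'
#' `S_q = sum_j P_j ln_q(1 / P_j)` over the nonzero probabilities, which
#' is evaluated through the algebraically identical closed form
#' `(sum_j P_j^q - 1) / (1 - q)`; the Shannon entropy `-sum P log P` is
#' used at `q = 1`.  Zero-probability terms contribute nothing (limit
#' convention).
#'
#' @param P A `pattern_distribution` or dense probability vector.
#' @param q Nonnegative weighting parameter; may be a vector.
#' @return Numeric vector of entropies, one per element of `q`.
#' @export
tsallis_entropy <- function(P, q) {
  parts <- .dist_parts(P)
  .tsallis_parts(parts, q)
}

.tsallis_parts <- function(parts, q) {
  p <- parts$p; w <- parts$w
  one <- .is_one(q)
  out <- numeric(length(q))
  if (any(!one)) {
    qs <- q[!one]
    out[!one] <- (.qab_sum(log(p), rep(0, length(p)), w, qs) - 1) / (1 - qs)
  }
  if (any(one)) out[one] <- -sum(w * p * log(p))
  out
}

#' Normalized Tsallis improved permutation entropy
#'
#' The Tsallis entropy divided by its maximum `ln_q(n_states)`, attained
#' by the uniform distribution; lies in `[0, 1]`.
#'
#' @inheritParams tsallis_entropy
#' @param n_states State count; taken from `P` when it is a
#'   `pattern_distribution`, required for a dense vector shorter than its
#'   alphabet.
#' @return Numeric vector in `[0, 1]`, one value per element of `q`.
#' @export
normalized_tipe <- function(P, q, n_states = NULL) {
  parts <- .dist_parts(P)
  if (!is.null(n_states)) parts$n <- n_states
  if (parts$n < 2) stop("need at least 2 states to normalize the entropy")
  .tsallis_parts(parts, q) / .max_entropy(parts$n, q)
}

# ln_q(n), the entropy of the uniform distribution over n states
.max_entropy <- function(n, q) {
  one <- .is_one(q)
  out <- numeric(length(q))
  out[!one] <- (exp((1 - q[!one]) * log(n)) - 1) / (1 - q[!one])
  out[one] <- log(n)
  out
}

# Dq(P, U) for P given as parts and U uniform over parts$n states.
# Dq = 1/2 Kq(P || M) + 1/2 Kq(U || M), M = (P + U)/2,
# Kq(A || B) = -sum_{A_j > 0} A_j ln_q(B_j / A_j)
#            = (1 - sum_j A_j^q B_j^(1-q)) / (1 - q).
# Off-support states (P_j = 0) enter only through Kq(U || M) and share
# the single value M = 1/(2n), so they are aggregated into one term.
.q_jsd_uniform <- function(parts, q) {
  p <- parts$p; w <- parts$w; n <- parts$n
  k <- sum(w)
  u <- 1 / n
  Mp <- (p + u) / 2
  M0 <- u / 2
  one <- .is_one(q)
  out <- numeric(length(q))
  if (any(!one)) {
    qs <- q[!one]; om <- 1 - qs
    KPM <- (1 - .qab_sum(log(p), log(Mp), w, qs)) / om
    KUM <- (1 - (.qab_sum(rep(log(u), length(p)), log(Mp), w, qs) +
                   (n - k) * exp(qs * log(u) + om * log(M0)))) / om
    out[!one] <- 0.5 * KPM + 0.5 * KUM
  }
  if (any(one)) {
    KPM <- sum(w * p * log(p / Mp))
    KUM <- sum(w * u * log(u / Mp)) + (n - k) * u * log(2)
    out[one] <- 0.5 * KPM + 0.5 * KUM
  }
  out
}

#' q-deformed Jensen-Shannon divergence
#'
#' Symmetrized q-Kullback divergence of two distributions against their
#' midpoint: `D_q(A, B) = 1/2 K_q(A || M) + 1/2 K_q(B || M)` with
#' `M = (A + B) / 2` and `K_q(A || B) = -sum_{A_j > 0} A_j ln_q(B_j / A_j)`.
#' At `q = 1` this is the classical Jensen-Shannon divergence.  The
#' q-deformation of the divergence kernel is isolated here so an
#' alternative deformation can be swapped in one place.
#'
#' @param A,B `pattern_distribution`s or dense probability vectors over
#'   the same state count.
#' @param q Nonnegative weighting parameter; may be a vector.
#' @return Numeric vector of divergences, one per element of `q`.
#' @export
q_jsd <- function(A, B, q) {
  nA <- if (inherits(A, "pattern_distribution")) A$n_states else length(A)
  nB <- if (inherits(B, "pattern_distribution")) B$n_states else length(B)
  if (nA != nB) stop("`A` and `B` must share the same state count")
  if (.is_uniform(B)) return(.q_jsd_uniform(.dist_parts(A), q))
  if (.is_uniform(A)) return(.q_jsd_uniform(.dist_parts(B), q))
  a <- as_probabilities(A)
  b <- as_probabilities(B)
  M <- (a + b) / 2
  out <- numeric(length(q))
  one <- .is_one(q)
  kq <- function(A_, qs) {
    i <- A_ > 0
    (1 - .qab_sum(log(A_[i]), log(M[i]), rep(1, sum(i)), qs)) / (1 - qs)
  }
  if (any(!one)) {
    qs <- q[!one]
    out[!one] <- 0.5 * kq(a, qs) + 0.5 * kq(b, qs)
  }
  if (any(one)) {
    k1 <- function(A_) { i <- A_ > 0; sum(A_[i] * log(A_[i] / M[i])) }
    out[one] <- 0.5 * k1(a) + 0.5 * k1(b)
  }
  out
}

.is_uniform <- function(d) {
  if (inherits(d, "pattern_distribution"))
    return(length(d$counts) == d$n_states && length(unique(d$counts)) == 1L)
  length(unique(d)) == 1L
}

#' Maximum q-deformed Jensen-Shannon divergence
#'
#' The normalizing constant of the disequilibrium: the divergence between
#' a one-point (delta) distribution and the uniform distribution, the
#' maximizer familiar from the complexity-entropy-plane literature.  A
#' numerical-maximization regression test guards this choice.
#'
#' @param n_states State count, integer >= 2.
#' @inheritParams tsallis_entropy
#' @return Numeric vector, one strictly positive value per element of `q`.
#' @export
max_q_jsd <- function(n_states, q) {
  if (n_states < 2) stop("`n_states` must be >= 2")
  n <- n_states
  u <- 1 / n
  Md <- (1 + u) / 2
  one <- .is_one(q)
  out <- numeric(length(q))
  if (any(!one)) {
    qs <- q[!one]; om <- 1 - qs
    KdM <- (1 - exp(om * log(Md))) / om
    KUM <- (1 - (exp(qs * log(u) + om * log(Md)) +
                   (n - 1) * exp(qs * log(u) + om * log(u / 2)))) / om
    out[!one] <- 0.5 * KdM + 0.5 * KUM
  }
  if (any(one))
    out[one] <- 0.5 * log(1 / Md) + 0.5 * (u * log(u / Md) + (n - 1) * u * log(2))
  out
}

#' Disequilibrium of a distribution
#'
#' The q-JSD between `P` and the uniform distribution, normalized by its
#' maximum ([max_q_jsd()]); lies in `[0, 1]`, 0 for the uniform
#' distribution and 1 for a one-point distribution.
#'
#' @inheritParams tsallis_entropy
#' @return Numeric vector in `[0, 1]`, one value per element of `q`.
#' @export
disequilibrium <- function(P, q) {
  parts <- .dist_parts(P)
  .q_jsd_uniform(parts, q) / max_q_jsd(parts$n, q)
}

#' Entropy-complexity point(s) of a distribution
#'
#' Evaluates, for each `q`, the raw Tsallis entropy `Sq`, the normalized
#' entropy `Hq`, the q-JSD from uniform `Dq` and its maximum `Dq_star`,
#' the disequilibrium `delta_q = Dq / Dq_star`, and the statistical
#' complexity `Cq = delta_q * Hq`.
#'
#' @inheritParams tsallis_entropy
#' @return A data frame with one row per element of `q` and columns
#'   `q`, `Sq`, `Hq`, `Dq`, `Dq_star`, `delta_q`, `Cq`.
#' @export
statistical_complexity <- function(P, q) {
  parts <- .dist_parts(P)
  if (parts$n < 2) stop("need at least 2 states")
  Sq <- .tsallis_parts(parts, q)
  Hq <- Sq / .max_entropy(parts$n, q)
  Dq <- .q_jsd_uniform(parts, q)
  Ds <- max_q_jsd(parts$n, q)
  dq <- Dq / Ds
  data.frame(q = q, Sq = Sq, Hq = Hq, Dq = Dq, Dq_star = Ds,
             delta_q = dq, Cq = dq * Hq)
}
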