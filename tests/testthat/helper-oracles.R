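# Independent brute-force reference implementations used to validate the
# package's fast paths.  Everything here recomputes from first principles
# (dense vectors, explicit loops) and shares no code with R/.

oracle_lnq <- function(x, q) {
  if (abs(q - 1) < 1e-12) log(x) else (x^(1 - q) - 1) / (1 - q)
}

oracle_shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Shannon Jensen-Shannon divergence via the entropy-of-mixture identity
oracle_jsd_shannon <- function(a, b) {
  m <- (a + b) / 2
  oracle_shannon(m) - 0.5 * oracle_shannon(a) - 0.5 * oracle_shannon(b)
}

oracle_tsallis <- function(p, q) {
  p <- p[p > 0]
  sum(p * oracle_lnq(1 / p, q))
}

# symmetrized q-Kullback divergence against the midpoint, dense and direct
oracle_q_jsd <- function(a, b, q) {
  m <- (a + b) / 2
  kq <- function(A, B) {
    i <- A > 0
    -sum(A[i] * oracle_lnq(B[i] / A[i], q))
  }
  0.5 * kq(a, m) + 0.5 * kq(b, m)
}

# dense enumerate-and-count pattern tally, explicit loops throughout
oracle_pattern_probs <- function(x, m, tau, L) {
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  y <- pnorm((x - mu) / sqrt(s2))
  n_rows <- length(y) - (m - 1) * tau
  delta <- (max(y) - min(y)) / L
  P <- numeric(L^m)
  for (j in seq_len(n_rows)) {
    row <- y[j + (0:(m - 1)) * tau]
    s1 <- min(floor((row[1] - min(y)) / delta), L - 1)
    sym <- numeric(m)
    sym[1] <- s1
    for (k in 2:m) {
      raw <- s1 + floor((row[k] - row[1]) / delta)
      sym[k] <- min(max(raw, 0), L - 1)
    }
    idx <- 0
    for (k in 1:m) idx <- idx * L + sym[k]
    P[idx + 1] <- P[idx + 1] + 1
  }
  P / n_rows
}

# end-to-end entropy/complexity at a single q, dense and direct
oracle_plane_point <- function(x, m, tau, L, q) {
  P <- oracle_pattern_probs(x, m, tau, L)
  n <- L^m
  U <- rep(1 / n, n)
  H <- oracle_tsallis(P, q) / oracle_lnq(n, q)
  delta <- c(1, rep(0, n - 1))
  D <- oracle_q_jsd(P, U, q)
  Ds <- oracle_q_jsd(delta, U, q)
  c(Hq = H, Cq = (D / Ds) * H)
}

random_distribution <- function(n) {
  p <- -log(runif(n))
  p / sum(p)
}
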