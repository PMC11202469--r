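test_that("q-logarithm reduces to ln at q = 1 and to x - 1 at q = 0", {
  expect_equal(q_log(exp(1), 1), 1)
  expect_equal(q_log(3, 0), 2)
  expect_equal(q_log(1, 2.7), 0)
  expect_equal(q_log(1, 0), 0)
  expect_error(q_log(-1, 2), "positive")
  expect_error(q_log(2, -0.5), "nonnegative")
})

test_that("Tsallis entropy matches the direct sum-of-q-logs oracle", {
  set.seed(21)
  for (rep in 1:10) {
    P <- random_distribution(sample(3:20, 1))
    for (q in c(0, 0.3, 1, 2.5, 10)) {
      expect_equal(tsallis_entropy(P, q), oracle_tsallis(P, q),
                   tolerance = 1e-10)
    }
  }
})

test_that("Tsallis entropy attains ln_q(n) at uniform and 0 at a point mass", {
  for (q in c(0, 0.5, 1, 2, 10)) {
    expect_equal(tsallis_entropy(uniform_distribution(16), q), q_log(16, q),
                 tolerance = 1e-12)
    expect_equal(tsallis_entropy(delta_distribution(16), q), 0)
  }
  expect_equal(tsallis_entropy(c(0.5, 0.5), 1), log(2))
})

test_that("Tsallis entropy is continuous through q = 1", {
  set.seed(5)
  for (rep in 1:10) {
    P <- random_distribution(8)
    sh <- oracle_shannon(P)
    expect_lt(abs(tsallis_entropy(P, 1 + 1e-6) - sh), 1e-4)
    expect_lt(abs(tsallis_entropy(P, 1 - 1e-6) - sh), 1e-4)
  }
})

test_that("normalized entropy spans [0, 1] with the right endpoints", {
  expect_equal(normalized_tipe(uniform_distribution(256), c(0, 1, 50)),
               c(1, 1, 1), tolerance = 1e-12)
  expect_equal(normalized_tipe(delta_distribution(256), c(0, 1, 50)),
               c(0, 0, 0))
  # binary Shannon entropy / ln 2
  expect_equal(normalized_tipe(c(0.75, 0.25), 1),
               oracle_shannon(c(0.75, 0.25)) / log(2), tolerance = 1e-12)
  expect_error(normalized_tipe(c(1), 1), "2 states")
})

test_that("q-JSD vanishes at equality, is symmetric, and matches oracles", {
  U <- rep(0.25, 4)
  for (q in c(0, 0.5, 1, 2, 10))
    expect_equal(q_jsd(U, U, q), 0, tolerance = 1e-14)
  set.seed(31)
  for (rep in 1:10) {
    a <- random_distribution(6)
    b <- random_distribution(6)
    for (q in c(0.5, 1, 2)) {
      expect_equal(q_jsd(a, b, q), q_jsd(b, a, q), tolerance = 1e-12)
      expect_equal(q_jsd(a, b, q), oracle_q_jsd(a, b, q), tolerance = 1e-10)
    }
    # at q = 1 the deformation reduces to the classical Shannon JSD
    u <- rep(1 / 6, 6)
    expect_equal(q_jsd(a, u, 1), oracle_jsd_shannon(a, u), tolerance = 1e-12)
  }
  expect_error(q_jsd(random_distribution(4), random_distribution(5), 1),
               "state count")
})

test_that("sparse uniform fast path agrees with the dense divergence", {
  set.seed(41)
  d <- ipe_distribution(rnorm(80), m = 3, L = 3)
  P <- as_probabilities(d)
  U <- rep(1 / 27, 27)
  for (q in c(0, 0.7, 1, 3, 40))
    expect_equal(q_jsd(d, uniform_distribution(27), q),
                 oracle_q_jsd(P, U, q), tolerance = 1e-10)
})

test_that("the point-mass distribution maximizes the q-JSD from uniform", {
  set.seed(55)
  for (n in c(4, 9, 16)) {
    u <- rep(1 / n, n)
    for (q in c(0.5, 1, 2)) {
      dstar <- max_q_jsd(n, q)
      # which state carries the mass is immaterial
      expect_equal(q_jsd(as_probabilities(delta_distribution(n, 3)), u, q),
                   dstar, tolerance = 1e-12)
      # random and optimizer-refined candidates never exceed it
      best <- 0
      for (rep in 1:50) {
        p <- random_distribution(n)^3
        p <- p / sum(p)
        best <- max(best, oracle_q_jsd(p, u, q))
      }
      opt <- optim(rep(0, n), function(z) {
        p <- exp(z) / sum(exp(z))
        -oracle_q_jsd(p, u, q)
      }, method = "BFGS")
      best <- max(best, -opt$value)
      expect_lte(best, dstar + 1e-9)
    }
  }
})

test_that("disequilibrium is 0 at uniform, 1 at a point mass, and oracle-exact between", {
  for (q in c(0, 0.5, 1, 2, 10, 100)) {
    expect_equal(disequilibrium(uniform_distribution(8), q), 0,
                 tolerance = 1e-12)
    expect_equal(disequilibrium(delta_distribution(8), q), 1,
                 tolerance = 1e-12)
  }
  set.seed(61)
  P <- random_distribution(4)
  u <- rep(0.25, 4)
  expect_equal(disequilibrium(P, 1),
               oracle_jsd_shannon(P, u) / oracle_jsd_shannon(c(1, 0, 0, 0), u),
               tolerance = 1e-12)
})

test_that("complexity vanishes at both extremes of order and factors as delta_q * Hq", {
  qv <- c(0, 0.5, 1, 2, 10, 100)
  expect_equal(statistical_complexity(uniform_distribution(64), qv)$Cq,
               rep(0, 6), tolerance = 1e-12)
  expect_equal(statistical_complexity(delta_distribution(64), qv)$Cq,
               rep(0, 6))
  set.seed(71)
  P <- random_distribution(16)
  pt <- statistical_complexity(P, qv)
  expect_equal(pt$Cq, pt$delta_q * pt$Hq, tolerance = 1e-12)
  expect_equal(pt$delta_q, pt$Dq / pt$Dq_star, tolerance = 1e-12)
})

test_that("entropy, disequilibrium and complexity stay bounded and finite at extreme q", {
  set.seed(81)
  qv <- c(seq(0, 5, by = 0.25), 10, 25, 50, 100)
  for (rep in 1:10) {
    P <- random_distribution(sample(c(4, 64, 1024), 1))
    pt <- statistical_complexity(P, qv)
    expect_true(all(is.finite(unlist(pt))))
    expect_true(all(pt$Hq >= -1e-12 & pt$Hq <= 1 + 1e-12))
    expect_true(all(pt$delta_q >= -1e-12 & pt$delta_q <= 1 + 1e-9))
    expect_true(all(pt$Cq >= -1e-12 & pt$Cq <= 1 + 1e-9))
  }
  # probabilities down to 1e-6 at q = 100 remain finite
  tiny <- c(1 - 1e-6 * 99, rep(1e-6, 99))
  pt <- statistical_complexity(tiny / sum(tiny), c(1, 50, 100))
  expect_true(all(is.finite(unlist(pt))))
})
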