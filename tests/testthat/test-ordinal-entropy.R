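test_that("embedding produces the delay windows", {
  W <- embed_series(1:5, embedding_config(m = 3, tau = 1))
  expect_equal(W, rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  W2 <- embed_series(1:5, embedding_config(m = 2, tau = 2))
  expect_equal(W2, rbind(c(1, 3), c(2, 4), c(3, 5)))
  expect_error(embed_series(1:4, embedding_config(m = 4, tau = 2)), "too short")
})

test_that("embedding config validates its parameters", {
  expect_error(embedding_config(m = 1), "m")
  expect_error(embedding_config(m = 9), "cap")
  expect_no_error(embedding_config(m = 9, max_m = 9))
  expect_error(embedding_config(tau = 0), "tau")
})

test_that("ordinal patterns sort ascending with index tie-breaking", {
  expect_equal(ordinal_pattern(c(9, 10, 6)), c(3, 1, 2))
  expect_equal(ordinal_pattern(c(5, 5, 5)), c(1, 2, 3))
  expect_equal(ordinal_pattern(c(1, 2, 3, 4)), 1:4)
  expect_error(ordinal_pattern(c(1, NA, 3)), "non-finite")
  # matches the naive selection-sort oracle, ties included
  set.seed(11)
  for (i in 1:50) {
    w <- sample(round(rnorm(6), 1))  # rounding creates ties
    expect_equal(ordinal_pattern(w), oracle_pattern(w))
  }
})

test_that("plain pattern distribution matches hand-enumerated frequencies", {
  d <- pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), embedding_config(m = 3))
  expect_equal(d$kind, "plain")
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  expect_equal(d$probs[["1-2-3"]], 2 / 5)
  expect_equal(d$probs[["3-1-2"]], 2 / 5)
  expect_equal(d$probs[["2-1-3"]], 1 / 5)
  expect_equal(d$support_count, 3)

  inc <- pattern_distribution(sort(rnorm(30)), embedding_config(m = 4))
  expect_equal(unname(inc$probs), 1)
  expect_equal(names(inc$probs), "1-2-3-4")

  const <- pattern_distribution(rep(2, 20), embedding_config(m = 3))
  expect_equal(names(const$probs), "1-2-3")  # tie rule collapses to identity
})

test_that("window weight is the population variance", {
  expect_equal(window_weight(c(10, 6, 11)), 14 / 3)
  expect_equal(window_weight(rep(3.7, 5)), 0)
  expect_equal(window_weight(c(0, 2)), 1)
})

test_that("weighted distribution accumulates window variances per pattern", {
  d <- pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), embedding_config(m = 3),
                            weighted = TRUE)
  # window variances: 38/9, 14/9, 26/9, 14/3, 98/9; total 218/9
  expect_equal(d$probs[["1-2-3"]], 52 / 218, tolerance = 1e-12)
  expect_equal(d$probs[["3-1-2"]], 124 / 218, tolerance = 1e-12)
  expect_equal(d$probs[["2-1-3"]], 42 / 218, tolerance = 1e-12)
  expect_equal(d$kind, "weighted")
})

test_that("entropies of the worked example match closed-form values", {
  x <- c(4, 7, 9, 10, 6, 11, 3)
  cfg <- embedding_config(m = 3)
  expect_equal(permutation_entropy(x, cfg),
               -(0.4 * log(0.4) + 0.4 * log(0.4) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  p <- c(52, 124, 42) / 218
  expect_equal(weighted_permutation_entropy(x, cfg), -sum(p * log(p)),
               tolerance = 1e-12)
})

test_that("long uniform noise approaches maximal normalized entropy", {
  set.seed(42)
  x <- runif(1e5)
  h <- permutation_entropy(x, embedding_config(m = 3, normalized = TRUE))
  expect_gt(h, 0.99)
  expect_lte(h, 1)
})

test_that("PE and WPE match the brute-force oracle on random series", {
  set.seed(7)
  n_checked <- 0
  for (rep in 1:25) {
    for (m in 2:5) {
      for (tau in 1:2) {
        x <- rnorm(50)
        if (rep %% 3 == 0) x <- round(x, 1)  # inject ties
        cfg <- embedding_config(m = m, tau = tau)
        expect_equal(permutation_entropy(x, cfg),
                     oracle_entropy(x, m, tau, weighted = FALSE),
                     tolerance = 1e-12)
        expect_equal(weighted_permutation_entropy(x, cfg),
                     oracle_entropy(x, m, tau, weighted = TRUE),
                     tolerance = 1e-12)
        n_checked <- n_checked + 2
      }
    }
  }
  expect_gte(n_checked, 200)
})

test_that("entropy bounds, monotone series and support size hold", {
  set.seed(8)
  for (rep in 1:20) {
    m <- sample(2:5, 1)
    x <- rnorm(60)
    cfg <- embedding_config(m = m)
    h <- permutation_entropy(x, cfg)
    hw <- weighted_permutation_entropy(x, cfg)
    expect_gte(h, 0); expect_lte(h, log(factorial(m)))
    expect_gte(hw, 0); expect_lte(hw, log(factorial(m)))
    hn <- permutation_entropy(x, embedding_config(m = m, normalized = TRUE))
    expect_gte(hn, 0); expect_lte(hn, 1)
    d <- pattern_distribution(x, cfg)
    expect_lte(d$support_count, min(factorial(m), d$n_windows))
  }
  expect_equal(permutation_entropy(seq_len(40), embedding_config()), 0)
  expect_equal(weighted_permutation_entropy(-seq_len(40), embedding_config()), 0)
})

test_that("entropies are invariant under positive affine rescaling", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(80)
    a <- exp(rnorm(1)); b <- rnorm(1)
    cfg <- embedding_config(m = 4)
    expect_equal(permutation_entropy(a * x + b, cfg), permutation_entropy(x, cfg),
                 tolerance = 1e-12)
    expect_equal(weighted_permutation_entropy(a * x + b, cfg),
                 weighted_permutation_entropy(x, cfg), tolerance = 1e-12)
  }
})

test_that("WPE reduces to PE when all window variances are equal", {
  set.seed(10)
  for (rep in 1:10) {
    # +/-1 increments: every m=2 window has variance (a-b)^2/4 = 1/4
    x <- cumsum(sample(c(-1, 1), 60, replace = TRUE))
    cfg <- embedding_config(m = 2)
    expect_equal(weighted_permutation_entropy(x, cfg),
                 permutation_entropy(x, cfg), tolerance = 1e-12)
  }
})

test_that("constant input gives degenerate weighted distribution and WPE 0", {
  expect_warning(d <- pattern_distribution(rep(1, 30), embedding_config(),
                                           weighted = TRUE), "degenerate")
  expect_true(d$degenerate)
  expect_equal(sum(d$probs), 0)
  expect_warning(h <- weighted_permutation_entropy(rep(5, 30), embedding_config()),
                 "constant")
  expect_equal(h, 0)
})
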