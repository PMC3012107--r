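test_that("count_rejections counts non-strictly and validates input", {
  expect_identical(count_rejections(c(0.01, 0.04, 0.2), 0.05), 2L)
  expect_identical(count_rejections(numeric(0), 0.05), 0L)
  # boundary p == gamma is included
  expect_identical(count_rejections(c(0.05, 0.05, 0.6), 0.05), 2L)
  expect_error(count_rejections(c(0.1, 1.5), 0.05), "index 2")
  expect_error(count_rejections(c(0.1, 0.2), 0), "gamma")
})

test_that("binomial critical value matches frozen enumeration oracle values", {
  expect_identical(binomial_critical_value(10, 0.5, 0.05), 9L)
  expect_identical(binomial_critical_value(1, 0.5, 0.05), 2L)
  # P(X >= 1) = 1023/1024 > 0.999, P(X >= 2) <= 0.999
  expect_identical(binomial_critical_value(10, 0.5, 0.999), 2L)
  expect_error(binomial_critical_value(-1, 0.5, 0.05), "non-negative")
})

test_that("meta-test p-value is the exact upper binomial tail", {
  expect_identical(meta_test_pvalue(17, 0.3, 0), 1)
  expect_identical(meta_test_pvalue(1000, 0.9, 0), 1)
  expect_equal(meta_test_pvalue(10, 0.5, 10), 1 / 1024)
  expect_equal(meta_test_pvalue(10, 0.5, 9), 11 / 1024)
  expect_error(meta_test_pvalue(10, 0.5, 11), "exceed")
})

test_that("critical value and meta p-value match brute-force pmf summation", {
  # moderate grid here; the exhaustive S <= 60 sweep runs with the
  # acceptance checks
  for (S in c(0L, 1L, 7L, 23L, 41L)) {
    for (gamma in c(0.05, 0.26, 0.9)) {
      for (alpha in c(0.01, 0.05, 0.15)) {
        expect_identical(binomial_critical_value(S, gamma, alpha),
                         as.integer(oracle_critical_value(S, gamma, alpha)),
                         info = sprintf("S=%d gamma=%g alpha=%g", S, gamma, alpha))
      }
      for (K in 0:S) {
        expect_equal(meta_test_pvalue(S, gamma, K), oracle_tail(S, gamma, K),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("effect count follows K - b + 1 with zero-clamp and cap", {
  expect_identical(n_effects(50, 40), 11L)
  expect_identical(n_effects(10, 20), 0L)
  expect_identical(n_effects(50, 40, K_at_alpha = 5, capped = TRUE), 5L)
  expect_error(n_effects(50, 40, capped = TRUE), "K_at_alpha")
})

test_that("sgof composes the pieces correctly on a hand-checkable set", {
  # ten p-values at 0.01 and ten at 0.9: K(0.05) = 10 and the
  # Binomial(20, 0.05) tail crosses 0.05 between b = 3 and b = 4, so N = 7
  pset <- pvalue_set(c(rep(0.01, 10), rep(0.9, 10)))
  res <- sgof(pset, gamma = 0.05, alpha = 0.05)
  expect_identical(res$K, 10L)
  expect_identical(res$b, 4L)
  expect_identical(res$n_effects, 7L)
  expect_identical(res$declared_ids, paste0("t", 1:7))  # stable input order
  expect_identical(res$threshold, 0.01)
  expect_identical(res$achieved_count, 10L)  # ties at the cut surface here

  null_res <- sgof(pvalue_set(rep(0.99, 5)), gamma = 0.05)
  expect_identical(null_res$K, 0L)
  expect_identical(null_res$meta_pvalue, 1)
  expect_identical(null_res$n_effects, 0L)
  expect_true(is.na(null_res$threshold))
  expect_true(is.na(null_res$efdr))

  # boundary: P(Bin(1, 0.05) >= 1) = 0.05 = alpha still rejects
  single <- sgof(pvalue_set(0.01), gamma = 0.05, alpha = 0.05)
  expect_identical(single$b, 1L)
  expect_identical(single$n_effects, 1L)

  expect_error(sgof(pvalue_set(numeric(0))), "empty")
})

test_that("sequential step-down form equals the closed form", {
  pset <- pvalue_set(c(rep(0.01, 10), rep(0.9, 10)))
  expect_identical(sgof_sequential(pset, 0.05, 0.05), 7L)
  expect_identical(sgof_sequential(pvalue_set(rep(0.99, 5)), 0.05), 0L)
  set.seed(2024)
  for (i in 1:200) {
    S <- sample(1:100, 1)
    p <- runif(S)^sample(c(1, 2, 4), 1)  # mix of flat and enriched sets
    gamma <- runif(1, 0.01, 0.9)
    alpha <- sample(c(0.01, 0.05, 0.15), 1)
    ps <- pvalue_set(p)
    expect_identical(sgof_sequential(ps, gamma, alpha),
                     sgof(ps, gamma, alpha)$n_effects)
  }
})

test_that("rejection of the intersection null is equivalent to N >= 1", {
  set.seed(99)
  for (i in 1:100) {
    p <- runif(sample(1:200, 1))^sample(c(1, 3), 1)
    gamma <- runif(1, 0.01, 0.9)
    res <- sgof(pvalue_set(p), gamma, 0.05)
    expect_identical(res$n_effects >= 1L, res$meta_pvalue <= 0.05 * (1 + 1e-9))
  }
})

test_that("K and b are non-decreasing in gamma", {
  set.seed(7)
  p <- runif(300)^2
  grid <- seq(0.01, 0.99, by = 0.01)
  K <- vapply(grid, function(g) count_rejections(p, g), integer(1))
  b <- vapply(grid, function(g) binomial_critical_value(300L, g, 0.05), integer(1))
  expect_true(all(diff(K) >= 0))
  expect_true(all(diff(b) >= 0))
})

test_that("threshold realizes the N-th order statistic and reports ties", {
  expect_equal(threshold_for_n(c(0.01, 0.02, 0.03, 0.9), 2),
               list(threshold = 0.02, achieved_count = 2L))
  expect_equal(threshold_for_n(c(0.5, 0.2), 0),
               list(threshold = NA_real_, achieved_count = 0L))
  tied <- threshold_for_n(c(0.01, 0.02, 0.02, 0.9), 2)
  expect_identical(tied$threshold, 0.02)
  expect_identical(tied$achieved_count, 3L)
  expect_error(threshold_for_n(c(0.1, 0.2), 3), "exceeds")
})

test_that("pi0 estimator is the mean of -log(1 - p)", {
  expect_equal(pi0_estimate(1 - exp(-1)), 1)
  expect_identical(pi0_estimate(c(0, 0)), 0)
  expect_warning(v <- pi0_estimate(c(0.5, 1)), "clamped")
  expect_true(is.finite(v) && v > 1)
})

test_that("plug-in eFDR follows S * q * min(pi0, 1) / N with clipping", {
  expect_equal(efdr(1000, 0.05, 0.9, 100), 0.45)
  expect_identical(efdr(1000, 0, 0.9, 10), 0)
  expect_identical(efdr(1000, 0.5, 1.0, 100), 1)   # raw 5 clipped
  expect_identical(efdr(1000, 0.5, 1.4, 100), 1)   # pi0 truncated at 1
  expect_true(is.na(efdr(1000, 0.1, 0.9, 0)))
})

test_that("capped variant never declares above alpha and is dominated", {
  set.seed(31)
  for (i in 1:50) {
    ps <- make_mixture(S = 400, effect_proportion = 0.2, w = 2)
    gamma <- runif(1, 0.05, 0.9)
    free <- sgof(ps, gamma, 0.05, capped = FALSE)
    cap <- sgof(ps, gamma, 0.05, capped = TRUE)
    expect_lte(cap$n_effects, free$n_effects)
    if (cap$n_effects > 0) {
      expect_true(all(ps$pvalues[cap$declared_idx] <= 0.05))
    }
    # uncapped declared p-values never exceed gamma
    if (free$n_effects > 0) {
      expect_true(all(ps$pvalues[free$declared_idx] <= gamma))
    }
  }
})

test_that("weak FWER holds under a moderate complete-null simulation", {
  set.seed(12)
  n_trials <- 400
  rejects <- replicate(n_trials, {
    p <- runif(300)
    sgof(pvalue_set(p), gamma = 0.26, alpha = 0.05)$n_effects >= 1
  })
  expect_lte(mean(rejects), 0.05 + 3 * sqrt(0.05 * 0.95 / n_trials))
})
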