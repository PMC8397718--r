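test_that("leading-term log-likelihood matches direct arithmetic", {
  expect_identical(leading_term_loglik(rank_counts(5), 1.7, W = 1), 0)
  expect_equal(leading_term_loglik(rank_counts(c(3, 2, 1)), 1, W = 3),
               3 * log(6 / 11) + 2 * log(3 / 11) + log(2 / 11),
               tolerance = 1e-12)
  # equals the identity-permutation term of the permutation likelihood
  cts <- rank_counts(c(8, 6, 3, 2, 1, 1))
  m <- zipf_model(1.3, 6)
  expect_equal(leading_term_loglik(cts, 1.3, W = 6),
               permutation_term_loglik(cts, 1:6, m), tolerance = 1e-12)
  expect_error(leading_term_loglik(rank_counts(c(2, 1)), 1.5, W = 1),
               "at least")
})

test_that("permutation-term log-likelihood follows the rank mapping", {
  # observed n = [8,6,3,2,1,1] arising through s = [2,1,5,3,4,6]:
  # the most probable event was seen 6 times, the 2nd most probable 8, ...
  cts <- rank_counts(c(8, 6, 3, 2, 1, 1))
  m <- zipf_model(1.1, 6)
  p <- pmf(m, 1:6)
  expect_equal(permutation_term_loglik(cts, c(2, 1, 5, 3, 4, 6), m),
               6 * log(p[1]) + 8 * log(p[2]) + 1 * log(p[3]) +
                 3 * log(p[4]) + 2 * log(p[5]) + 1 * log(p[6]),
               tolerance = 1e-12)
  # uniform model: every mapping gives N log(1/W)
  u <- zipf_model(0, 6)
  for (s in list(1:6, 6:1, c(3, 1, 2, 6, 5, 4)))
    expect_equal(permutation_term_loglik(cts, s, u), 21 * log(1 / 6),
                 tolerance = 1e-12)
  expect_error(permutation_term_loglik(cts, c(1, 1, 2, 3, 4, 5), m),
               "permutation")
})

test_that("log-permanent engines are exact and agree with direct expansion", {
  expect_equal(log_permanent(diag(3)), 0)
  expect_equal(log_permanent(matrix(1, 4, 4)), log(24), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    W <- sample(2:7, 1)
    A <- matrix(runif(W * W, 0.05, 1), W, W)
    ln <- log_permanent(A, method = "naive")
    lr <- log_permanent(A, method = "ryser")
    expect_equal(lr, ln, tolerance = 1e-10)
    expect_equal(ln, log(perm_oracle(A)), tolerance = 1e-10)
  }
  expect_error(log_permanent(matrix(1, 26, 26)), "capped")
})

test_that("full likelihood: closed forms, padding, dominance", {
  expect_equal(full_loglik(rank_counts(7), 1.4, W = 1), 0, tolerance = 1e-12)
  # two-permutation hand sum: p1 = 2/3, p2 = 1/3
  expect_equal(full_loglik(c(3, 1), 1, W = 2), log(10 / 81), tolerance = 1e-12)
  # zero-padding: unobserved events contribute factor 1 terms, and the
  # likelihood still dominates its leading term
  set.seed(8)
  for (i in 1:5) {
    W <- sample(3:7, 1)
    cts <- rank_counts(rand_counts(sample.int(W, 1)))
    for (l in seq(0.3, 3, length.out = 25)) {
      expect_gte(full_loglik(cts, l, W) + 1e-10,
                 leading_term_loglik(cts, l, W))
    }
  }
})

test_that("likelihood derivative matches finite differences and vanishes at the MLE", {
  expect_equal(full_loglik_gradient(rank_counts(4), 2, W = 1), 0)
  l <- 1.2; h <- 1e-6
  fd <- (exp(full_loglik(c(3, 2, 1), l + h, 3)) -
           exp(full_loglik(c(3, 2, 1), l - h, 3))) / (2 * h)
  expect_equal(full_loglik_gradient(c(3, 2, 1), l, 3), fd, tolerance = 1e-4)
  fit <- mle_full(c(10, 3, 3, 2, 1, 1), 6)
  g <- full_loglik_gradient(c(10, 3, 3, 2, 1, 1), fit$lambda, 6)
  expect_lt(abs(g / exp(full_loglik(c(10, 3, 3, 2, 1, 1), fit$lambda, 6))),
            1e-4)
})

test_that("dual-number Ryser derivative agrees with enumeration for W > 8", {
  # score from the Ryser path vs a finite difference of the log-likelihood
  cts <- rank_counts(c(9, 5, 4, 3, 2, 2, 1, 1, 1, 1))
  W <- 10; l <- 1.3; h <- 1e-5
  sc <- zipfbias:::full_loglik_core(cts, l, W, want_score = TRUE)$score
  fd <- (full_loglik(cts, l + h, W) - full_loglik(cts, l - h, W)) / (2 * h)
  expect_equal(sc, fd, tolerance = 1e-5)
})

test_that("leading-term finite-W MLE reproduces the worked example", {
  fit <- mle_leading_finite(rank_counts(c(10, 3, 3, 2, 1, 1)), W = 6)
  expect_equal(round(fit$lambda, 2), 1.27)
  # all-equal counts: best power law is uniform, boundary at 0
  expect_warning(fit0 <- mle_leading_finite(rank_counts(c(5, 5, 5, 5)), W = 4),
                 "boundary")
  grid <- seq(0, 3, by = 0.005)
  ll <- vapply(grid, function(l)
    leading_term_loglik(rank_counts(c(5, 5, 5, 5)), l, 4), numeric(1))
  expect_equal(grid[which.max(ll)], 0)
  expect_equal(fit0$lambda, 0)
  expect_error(mle_leading_finite(rank_counts(7), W = 1), "single-event")
})

test_that("full-likelihood MLE reproduces the worked example and its ordering", {
  cts <- rank_counts(c(10, 3, 3, 2, 1, 1))
  fit_full <- mle_full(cts, 6)
  fit_lead <- mle_leading_finite(cts, 6)
  expect_equal(round(fit_full$lambda, 2), 1.16)
  expect_lt(fit_full$lambda, fit_lead$lambda)
  # invariance to relabeling among equal counts (input order irrelevant)
  fit_perm <- mle_full(c(3, 10, 1, 2, 3, 1), 6)
  expect_equal(fit_perm$lambda, fit_full$lambda, tolerance = 1e-8)
})

test_that("both likelihood curves have a unique interior maximum", {
  cts <- rank_counts(c(10, 3, 3, 2, 1, 1))
  grid <- seq(0.5, 2.5, by = 0.02)
  lead <- vapply(grid, function(l) leading_term_loglik(cts, l, 6), numeric(1))
  full <- vapply(grid, function(l) full_loglik(cts, l, 6), numeric(1))
  for (curve in list(lead, full)) {
    signs <- sign(diff(curve))
    expect_equal(sum(diff(signs) != 0), 1)   # rises then falls, once
  }
  expect_equal(grid[which.max(lead)], 1.27, tolerance = 0.02)
  expect_equal(grid[which.max(full)], 1.16, tolerance = 0.02)
})

test_that("unbounded leading-term MLE rejects degenerate data", {
  expect_error(mle_leading_unbounded(rank_counts(10)), "degenerate")
})

test_that("unbounded leading-term MLE is consistent on a-priori-ranked data", {
  # small-scale check; the full-size version lives with the acceptance runs
  ests <- vapply(1:5, function(s) {
    samp <- sample_counts(zipf_model(1.5), 20000, seed = 400 + s)
    mle_leading_unbounded(samp$counts, ranks = samp$prob_rank)$lambda
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1.5), 0.03)
  # ... while the same likelihood on empirical ranks is biased upward at
  # lambda near 1
  ests_emp <- vapply(1:5, function(s) {
    samp <- sample_counts(zipf_model(1.1), 20000, seed = 500 + s)
    mle_leading_unbounded(samp$counts)$lambda
  }, numeric(1))
  expect_gt(mean(ests_emp), 1.1)
})

test_that("likelihood_matrix stores row-scaled entries consistently", {
  lmat <- likelihood_matrix(rank_counts(c(4, 2, 1)), 1.2, W = 3)
  expect_true(all(lmat$entries > 0 & lmat$entries <= 1))
  expect_true(all(is.finite(lmat$row_log_scale)))
  expect_equal(lmat$log_entries,
               log(lmat$entries) + lmat$row_log_scale, tolerance = 1e-12)
  expect_equal(log_permanent(lmat), full_loglik(c(4, 2, 1), 1.2, 3),
               tolerance = 1e-12)
})
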