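test_that("normalizer matches closed forms and brute-force summation", {
  expect_equal(normalizer(2, Inf), pi^2 / 6, tolerance = 1e-12)
  expect_equal(normalizer(1, 3), 11 / 6, tolerance = 1e-12)
  expect_equal(normalizer(1.7, 50, q = 3), sum((1:50 + 3)^-1.7),
               tolerance = 1e-12)
  # divergence / domain errors
  expect_error(normalizer(1, Inf), "diverges")
  expect_error(normalizer(0.8, Inf), "diverges")
  expect_error(normalizer(1.5, 0), "positive integer")
  expect_error(normalizer(1.5, 10, q = -1), "non-negative")
  # strictly decreasing in lambda for fixed W >= 2
  for (W in c(2, 10, 1000)) {
    z <- vapply(seq(0.2, 3, by = 0.2), normalizer, numeric(1), W = W)
    expect_true(all(diff(z) < 0))
  }
})

test_that("pmf matches closed forms, sums to one, and ZM reduces at q = 0", {
  expect_equal(pmf(zipf_model(1, W = 2), 1), 2 / 3, tolerance = 1e-12)
  expect_equal(pmf(zipf_model(2, Inf), 2), 0.25 / pracma::zeta(2),
               tolerance = 1e-12)
  expect_equal(pmf(zipf_mandelbrot_model(1.5, 0, 10), 4),
               pmf(zipf_model(1.5, 10), 4), tolerance = 1e-15)
  for (m in list(zipf_model(0.7, 40), zipf_mandelbrot_model(1.3, 5, 25))) {
    p <- pmf(m, seq_len(m$W))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) < 0))
  }
  expect_error(pmf(zipf_model(1, 5), 6), "out of range")
  expect_error(pmf(zipf_model(1, 5), 0), "out of range")
})

test_that("normalizer derivative agrees with finite differences and zeta'", {
  expect_identical(normalizer_derivative(1.4, 1), 0)
  h <- 1e-6
  fd <- (normalizer(1.5 + h, 100) - normalizer(1.5 - h, 100)) / (2 * h)
  expect_equal(normalizer_derivative(1.5, 100), fd, tolerance = 1e-6)
  expect_equal(normalizer_derivative(2, Inf), -0.9375482543,
               tolerance = 1e-9)
  for (W in c(2, 10, Inf))
    expect_lt(normalizer_derivative(1.8, W), 0)
})

test_that("Euler-Maclaurin zeta agrees with pracma's zeta (dual route)", {
  for (s in c(1.01, 1.1, 1.5, 2, 3, 3.9))
    expect_equal(zipfbias:::zeta_em(s), pracma::zeta(s), tolerance = 1e-12)
  # derivative vs central differences of pracma's zeta; s = 1.01 excluded
  # because near the pole the finite difference's own truncation error
  # (~ h^2 zeta''' / 6) dominates the comparison
  for (s in c(1.1, 1.5, 2, 3, 3.9)) {
    h <- 1e-5
    fd <- (pracma::zeta(s + h) - pracma::zeta(s - h)) / (2 * h)
    expect_equal(zipfbias:::zeta_deriv(s), fd, tolerance = 1e-7)
  }
})

test_that("sample_counts: degenerate case, determinism, head frequency", {
  s1 <- sample_counts(zipf_model(2, W = 1), 10, seed = 1)
  expect_equal(as.integer(s1$counts), 10L)
  m <- zipf_model(1.5)
  a <- sample_counts(m, 5000, seed = 99)
  b <- sample_counts(m, 5000, seed = 99)
  expect_identical(as.integer(a$counts), as.integer(b$counts))
  expect_identical(a$prob_rank, b$prob_rank)
  # rank-1 frequency within a 4-sigma binomial interval of pmf(1)
  big <- sample_counts(m, 1e5, seed = 7)
  p1 <- pmf(m, 1)
  n1 <- as.integer(big$counts)[which(big$prob_rank == 1)]
  expect_lt(abs(n1 - 1e5 * p1), 4 * sqrt(1e5 * p1 * (1 - p1)))
})

test_that("Zipf-Mandelbrot sampling with q = 0 equals Zipf sampling per seed", {
  zm <- sample_counts(zipf_mandelbrot_model(1.4, 0, Inf), 2000, seed = 5)
  zf <- sample_counts(zipf_model(1.4, Inf), 2000, seed = 5)
  expect_identical(as.integer(zm$counts), as.integer(zf$counts))
  fin_zm <- sample_counts(zipf_mandelbrot_model(1.1, 0, 50), 1000, seed = 6)
  fin_zf <- sample_counts(zipf_model(1.1, 50), 1000, seed = 6)
  expect_identical(as.integer(fin_zm$counts), as.integer(fin_zf$counts))
})

test_that("sampler passes chi-square goodness of fit over the head ranks", {
  m <- zipf_model(1.5)
  p20 <- pmf(m, 1:20)
  probs <- c(p20, 1 - sum(p20))
  rejections <- 0L
  for (s in 1:20) {
    samp <- sample_counts(m, 1e5, seed = 3000 + s)
    cnt <- integer(20)
    idx <- match(1:20, samp$prob_rank)
    cnt[!is.na(idx)] <- as.integer(samp$counts)[idx[!is.na(idx)]]
    x <- c(cnt, 1e5 - sum(cnt))
    pval <- suppressWarnings(stats::chisq.test(x, p = probs)$p.value)
    if (pval < 0.001) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("finite-W sampling mapping is a valid permutation", {
  samp <- sample_counts(zipf_model(1.2, W = 30), 500, seed = 11)
  expect_identical(sort(samp$mapping), 1:30)
  # observed events occupy the first empirical ranks in count order
  expect_identical(samp$mapping[samp$prob_rank],
                   seq_along(samp$prob_rank))
})

test_that("model parameters round-trip through JSON", {
  for (m in list(zipf_model(1.3, Inf), zipf_mandelbrot_model(1.2, 4, 100))) {
    m2 <- model_from_json(model_to_json(m))
    expect_equal(m2$lambda, m$lambda)
    expect_equal(m2$q, m$q)
    expect_equal(m2$W, m$W)
    expect_equal(m2$family, m$family)
  }
})
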